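#' Marginal log-likelihood of the heteroscedastic SEM
#'
#' Sum over observations of the log density of
#' \eqn{y_i \sim N(0,\; \Lambda \Sigma_\omega \Lambda^T +
#' \Psi_{\varepsilon i})}, where \eqn{\Psi_{\varepsilon i}} carries the
#' per-observation variances `psi_eps[k] * m(z_i)` for heteroscedastic
#' indicators.  The two-indicator case is evaluated in closed form
#' (vectorised); larger models fall back to per-observation Cholesky
#' factorisations.
#'
#' @param data A `sem_dataset` (its `z` drives the variance law).
#' @param spec A [sem_spec()] (defaults to the one in `params`).
#' @param params A [model_parameters()].
#' @return Finite scalar log-likelihood.
#' @export
log_likelihood <- function(data, spec = params$spec, params) {
  y <- as.matrix(data$y)
  n <- nrow(y); p <- ncol(y)
  stopifnot(p == spec$p)
  mult <- if (any(spec$heteroscedastic)) {
    variance_profile(params$law, data$z)
  } else rep(1, n)
  V <- .error_variances(params, mult)
  So <- implied_latent_covariance(spec, params)
  B <- params$Lambda %*% So %*% t(params$Lambda)
  if (p == 1L) {
    s2 <- B[1, 1] + V[, 1]
    ll <- sum(stats::dnorm(y[, 1], 0, sqrt(s2), log = TRUE))
  } else if (p == 2L) {
    a <- B[1, 1] + V[, 1]
    d <- B[2, 2] + V[, 2]
    b <- B[1, 2]
    det <- a * d - b^2
    if (any(det <= 0)) stop("per-observation covariance not positive definite")
    quad <- (y[, 1]^2 * d - 2 * y[, 1] * y[, 2] * b + y[, 2]^2 * a) / det
    ll <- sum(-log(2 * pi) - 0.5 * log(det) - 0.5 * quad)
  } else {
    ll <- 0
    for (i in seq_len(n)) {
      Ci <- B
      diag(Ci) <- diag(Ci) + V[i, ]
      R <- tryCatch(chol(Ci), error = function(e) {
        stop("per-observation covariance not positive definite")
      })
      q <- sum(backsolve(R, y[i, ], transpose = TRUE)^2)
      ll <- ll - 0.5 * (p * log(2 * pi) + 2 * sum(log(diag(R))) + q)
    }
  }
  if (!is.finite(ll)) stop("non-finite log-likelihood")
  ll
}
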