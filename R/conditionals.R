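# Full conditional draws.  Each function performs ONE draw from the stated
# conditional using R's global RNG; run_gibbs wires them into a sweep.

# interpret an `omega` argument as per-observation variance multipliers
.as_multipliers <- function(omega) {
  if (inherits(omega, "disturbance_cov")) {
    if (omega$law$scale <= 0) stop("disturbance covariance has zero scale")
    omega$diagonal / omega$law$scale
  } else {
    as.numeric(omega)
  }
}

#' Draw one loading row from its normal full conditional
#'
#' Generalized-least-squares update for a loading row under an independent
#' normal prior: with weights \eqn{w_i = h / m_i}, the conditional is
#' \eqn{N(\mu^*, P^{*-1})} with
#' \eqn{P^* = H_0 + h X^T \Omega^{-1} X} and
#' \eqn{\mu^* = P^{*-1}(H_0 \lambda_0 + h X^T \Omega^{-1} y)} — a
#' precision-weighted compromise between the prior and the GLS evidence.
#'
#' @param y_col Response vector (one indicator column, fixed-loading offset
#'   already removed).
#' @param regressors n x r matrix of latent-score regressors.
#' @param precision Global error precision \eqn{h} (scalar, > 0).
#' @param omega Per-observation variance multipliers \eqn{m_i} (numeric
#'   vector) or a [build_omega()] result.
#' @param prior_mean Length-r prior mean \eqn{\lambda_0}.
#' @param prior_precision Prior precision: scalar, length-r vector
#'   (diagonal), or r x r matrix.
#' @return Length-r numeric draw.
#' @export
draw_loading_row <- function(y_col, regressors, precision, omega,
                             prior_mean, prior_precision) {
  X <- as.matrix(regressors)
  n <- nrow(X); r <- ncol(X)
  m <- .as_multipliers(omega)
  stopifnot(length(y_col) == n, length(m) == n, all(m > 0), precision > 0)
  H0 <- prior_precision
  if (!is.matrix(H0)) H0 <- diag(as.numeric(H0), r, r)
  w <- precision / m
  P <- H0 + crossprod(X * w, X)
  b <- H0 %*% prior_mean + crossprod(X, w * y_col)
  P <- (P + t(P)) / 2
  R <- tryCatch(chol(P), error = function(e) {
    stop("combined loading precision is not positive definite: ",
         conditionMessage(e))
  })
  mu <- backsolve(R, backsolve(R, b, transpose = TRUE))
  drop(mu + backsolve(R, stats::rnorm(r)))
}

#' Draw an error precision from its gamma full conditional
#'
#' \eqn{h \mid \cdot \sim \mathrm{Gamma}(\alpha_0 + n/2,\;
#' \beta_0 + \tfrac12 \sum_i e_i^2 / m_i)}: the multiplier-weighted residual
#' sum of squares enters the rate.  With `length(residuals) == 0` this is a
#' draw from the prior.
#'
#' @param residuals Residual vector (may be empty).
#' @param omega_multipliers Positive multipliers \eqn{m_i}, same length.
#' @param alpha0,beta0 Prior gamma shape and rate (> 0).
#' @return One positive precision draw.
#' @export
draw_precision <- function(residuals, omega_multipliers, alpha0, beta0) {
  n <- length(residuals)
  stopifnot(length(omega_multipliers) == n, alpha0 > 0, beta0 > 0)
  if (n > 0 && any(omega_multipliers <= 0)) {
    stop("variance multipliers must be strictly positive")
  }
  rate <- beta0 + if (n) 0.5 * sum(residuals^2 / omega_multipliers) else 0
  if (!is.finite(rate) || rate <= 0) stop("non-positive gamma rate")
  stats::rgamma(1L, shape = alpha0 + n / 2, rate = rate)
}

#' Draw the exogenous factor covariance from its inverse-Wishart conditional
#'
#' \eqn{\Phi \mid \xi \sim IW(v_0 + n,\; V_0 + \sum_i \xi_i \xi_i^T)}.
#' With zero rows this is a prior draw (mean \eqn{V_0 / (v_0 - q_2 - 1)}
#' when it exists).
#'
#' @param exogenous_scores n x q2 matrix of exogenous latent scores (may
#'   have zero rows).
#' @param v0 Prior degrees of freedom (> q2 - 1).
#' @param V0 Prior scale matrix (symmetric positive definite).
#' @return Symmetric positive-definite q2 x q2 draw.
#' @export
draw_factor_cov <- function(exogenous_scores, v0, V0) {
  X <- as.matrix(exogenous_scores)
  q2 <- ncol(V0 <- as.matrix(V0))
  n <- nrow(X)
  S <- V0 + if (n) crossprod(X) else 0
  S <- (S + t(S)) / 2
  if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("inverse-Wishart scale is not positive definite")
  }
  W <- stats::rWishart(1L, df = v0 + n, Sigma = solve(S))[, , 1L]
  out <- solve(W)
  (out + t(out)) / 2
}

#' Draw the latent scores from their conditional normal
#'
#' Per observation, \eqn{\omega_i \mid y_i \sim N(\Sigma_\omega \Lambda^T
#' C_i^{-1} y_i,\; \Sigma_\omega - \Sigma_\omega \Lambda^T C_i^{-1} \Lambda
#' \Sigma_\omega)} with \eqn{C_i = \Lambda \Sigma_\omega \Lambda^T +
#' \Psi_{\varepsilon i}} carrying the per-observation heteroscedastic
#' variances.  Conditional covariances are symmetrised and jittered by at
#' most 1e-8 before factorisation.
#'
#' @param y n x p matrix of observed indicators.
#' @param params A [model_parameters()] (its `law` and `psi_eps` determine
#'   the per-observation error variances together with `driver`).
#' @param sigma_omega Latent covariance \eqn{\Sigma_\omega}; defaults to
#'   [implied_latent_covariance()].
#' @param driver Driver covariate (needed when any indicator is
#'   heteroscedastic); `NULL` means all multipliers 1.
#' @return n x (q1+q2) matrix of latent score draws.
#' @export
draw_latent_scores <- function(y, params, sigma_omega = NULL, driver = NULL) {
  spec <- params$spec
  y <- as.matrix(y)
  n <- nrow(y)
  if (is.null(sigma_omega)) {
    sigma_omega <- implied_latent_covariance(spec, params)
  }
  mult <- if (is.null(driver)) rep(1, n) else
    variance_profile(params$law, driver)
  V <- .error_variances(params, mult)        # n x p
  .draw_scores_raw(y, V, params$Lambda, sigma_omega)
}

# n x p matrix of per-observation error variances
.error_variances <- function(params, mult) {
  spec <- params$spec
  V <- matrix(rep(params$psi_eps, each = length(mult)),
              nrow = length(mult))
  if (any(spec$heteroscedastic)) {
    V[, spec$heteroscedastic] <- V[, spec$heteroscedastic, drop = FALSE] *
      mult
  }
  V
}

# unnormalised log conditional density of the free variance-law coefficient
.varlaw_logpost <- function(theta, mfun, sq_resid, n_indicators, precision,
                            prior_mean, prior_sd) {
  m <- mfun(theta)
  if (is.null(m) || any(!is.finite(m)) || any(m <= 0)) return(-Inf)
  -0.5 * n_indicators * sum(log(m)) -
    0.5 * precision * sum(sq_resid / m) +
    stats::dnorm(theta, prior_mean, prior_sd, log = TRUE)
}

# multiplier evaluator in the identified (scale-fixed) parameterisation
.law_mfun <- function(form, driver) {
  z <- as.numeric(driver)
  switch(form,
    double_log      = { lz <- log(z); function(th) exp(th * lz) },
    linear          = function(th) 1 + th * z,
    linear_inverse  = { iz <- 1 / z; function(th) 1 + th * iz },
    linear_absolute = { az <- abs(z); function(th) (1 + th * az)^2 }
  )
}

#' Metropolis update of the free variance-law coefficient
#'
#' One Gaussian random-walk Metropolis-Hastings step targeting the
#' conditional density \eqn{\propto \prod_i m_i^{-p_h/2}
#' \exp\{-(h/2)\sum_i q_i / m_i\} \times \pi(\theta)}, where \eqn{q_i} is
#' the squared-residual sum over the \eqn{p_h} heteroscedastic indicators
#' and \eqn{\pi} the normal prior.  Proposals producing an inadmissible
#' (non-positive) variance profile are rejected outright.  A zero
#' `proposal_scale` leaves the chain at its current state (every "proposal"
#' accepted unchanged).
#'
#' @param residuals n-vector or n x p_h matrix of measurement residuals of
#'   the heteroscedastic indicators.
#' @param driver Driver covariate.
#' @param form Law form string.
#' @param current Current free-coefficient value (scalar).
#' @param precision Global error precision \eqn{h}.
#' @param prior_mean,prior_sd Normal prior on the coefficient.
#' @param proposal_scale Random-walk proposal standard deviation.
#' @param normalize Target the sample-normalised parameterisation (mean
#'   multiplier 1 over `driver`); used by the Gibbs engine, see
#'   [variance_law()].
#' @return List with `coeffs` (new value), `accepted` (logical) and `law`
#'   (a [variance_law()] at the new value, unit scale).
#' @export
draw_varlaw_coeffs <- function(residuals, driver, form, current,
                               precision, prior_mean = 0, prior_sd = 2,
                               proposal_scale = 0.1, normalize = FALSE) {
  E <- as.matrix(residuals)
  sq <- rowSums(E^2)
  ph <- ncol(E)
  mfun <- .law_mfun(form, driver)
  if (normalize) {
    mfun0 <- mfun
    mfun <- function(th) {
      m <- mfun0(th)
      if (any(m <= 0) || any(!is.finite(m))) return(m)
      m / mean(m)
    }
  }
  lp_cur <- .varlaw_logpost(current, mfun, sq, ph, precision,
                            prior_mean, prior_sd)
  if (!is.finite(lp_cur)) stop("current variance-law state is inadmissible")
  prop <- current + stats::rnorm(1L, 0, proposal_scale)
  lp_prop <- .varlaw_logpost(prop, mfun, sq, ph, precision,
                             prior_mean, prior_sd)
  accept <- log(stats::runif(1L)) < (lp_prop - lp_cur)
  theta <- if (accept) prop else current
  cf <- if (form == "double_log") c(lambda0 = 0, lambda1 = theta) else
    c(lambda1 = 1, lambda2 = theta)
  list(coeffs = theta, accepted = accept,
       law = variance_law(form, cf, scale = 1, normalize = normalize))
}
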