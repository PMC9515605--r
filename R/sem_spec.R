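#' Specify the skeleton of a structural equation model
#'
#' A `sem_spec` fixes the dimensions and free/fixed pattern of a SEM with
#' measurement model \eqn{y_i = \Lambda \omega_i + \varepsilon_i} and
#' structural model \eqn{\eta_i = \Pi \eta_i + \Gamma \xi_i + \delta_i},
#' where \eqn{\omega_i = (\eta_i, \xi_i)} stacks the endogenous and exogenous
#' latent variables.
#'
#' Patterns are numeric matrices in which `NA` marks a free (estimated)
#' entry and any number a fixed value.  The diagonal of `Pi` is structurally
#' zero.  Identification requires either a fixed exogenous factor covariance
#' (`phi_fixed`) or at least one fixed non-zero loading per factor; the
#' constructor rejects specs satisfying neither.
#'
#' @param loading_pattern p x (q1+q2) pattern for the loading matrix
#'   \eqn{\Lambda} (`NA` = free).
#' @param n_endogenous Number of endogenous latent variables \eqn{q_1}.
#' @param n_exogenous Number of exogenous latent variables \eqn{q_2}.
#' @param Pi q1 x q1 pattern for the endogenous coefficient matrix
#'   (diagonal must be fixed 0).  `NULL` when `n_endogenous == 0`.
#' @param Gamma q1 x q2 pattern for the exogenous coefficient matrix.
#' @param phi_fixed Optional fixed q2 x q2 exogenous factor covariance; when
#'   `NULL`, \eqn{\Phi} is estimated with an inverse-Wishart prior.
#' @param heteroscedastic Logical vector, length p: which indicators' error
#'   variances follow the heteroscedastic law (sharing the global precision
#'   `h`).  Indicators left `FALSE` get individual homoscedastic variances.
#' @return Object of class `sem_spec`.
#' @examples
#' # the default two-indicator one-factor fixture
#' sp <- two_indicator_spec()
#' sp$p; sp$q2
#' @export
sem_spec <- function(loading_pattern, n_endogenous = 0L, n_exogenous = 1L,
                     Pi = NULL, Gamma = NULL, phi_fixed = NULL,
                     heteroscedastic = NULL) {
  loading_pattern <- as.matrix(loading_pattern)
  p <- nrow(loading_pattern)
  q1 <- as.integer(n_endogenous)
  q2 <- as.integer(n_exogenous)
  k <- q1 + q2
  if (ncol(loading_pattern) != k) {
    stop("loading_pattern must have q1 + q2 = ", k, " columns")
  }
  if (q2 < 1L) stop("at least one exogenous latent variable is required")
  if (q1 > 0L) {
    if (is.null(Pi)) Pi <- matrix(0, q1, q1)
    if (is.null(Gamma)) Gamma <- matrix(NA_real_, q1, q2)
    Pi <- as.matrix(Pi); Gamma <- as.matrix(Gamma)
    stopifnot(dim(Pi) == c(q1, q1), dim(Gamma) == c(q1, q2))
    if (any(is.na(diag(Pi))) || any(diag(Pi) != 0)) {
      stop("the diagonal of Pi must be fixed at zero")
    }
  } else {
    Pi <- matrix(0, 0, 0); Gamma <- matrix(0, 0, q2)
  }
  if (!is.null(phi_fixed)) {
    phi_fixed <- as.matrix(phi_fixed)
    stopifnot(dim(phi_fixed) == c(q2, q2))
    if (!isSymmetric(phi_fixed, tol = 1e-10) ||
        any(eigen(phi_fixed, symmetric = TRUE,
                  only.values = TRUE)$values <= 0)) {
      stop("phi_fixed must be symmetric positive definite")
    }
  } else {
    # each factor needs an anchor loading fixed at a non-zero value
    for (j in seq_len(k)) {
      col <- loading_pattern[, j]
      anchored <- any(!is.na(col) & col != 0)
      if (!anchored) {
        stop("unidentified spec: factor ", j, " has no fixed non-zero ",
             "loading and the factor covariance is not fixed")
      }
    }
  }
  if (is.null(heteroscedastic)) heteroscedastic <- rep(TRUE, p)
  stopifnot(is.logical(heteroscedastic), length(heteroscedastic) == p)
  if (!any(heteroscedastic)) {
    # degenerate but allowed: fully homoscedastic model, no global h
    warning("no indicator is flagged heteroscedastic; the variance law ",
            "will not be estimated")
  }
  structure(list(p = p, q1 = q1, q2 = q2, k = k,
                 loading_pattern = loading_pattern,
                 Pi = Pi, Gamma = Gamma, phi_fixed = phi_fixed,
                 heteroscedastic = heteroscedastic),
            class = "sem_spec")
}

#' @export
print.sem_spec <- function(x, ...) {
  cat("<sem_spec> p =", x$p, " q1 =", x$q1, " q2 =", x$q2,
      if (is.null(x$phi_fixed)) " (Phi free)" else " (Phi fixed)", "\n")
  invisible(x)
}

#' The default two-indicator, one-factor model skeleton
#'
#' Two indicators load freely on a single exogenous factor whose variance is
#' fixed at 1 for identification; both indicators' errors follow the
#' heteroscedastic law.  This is the configuration used throughout the
#' simulation study.
#'
#' @param p Number of indicators (default 2); all load on the single factor.
#' @return A [sem_spec()].
#' @export
two_indicator_spec <- function(p = 2L) {
  sem_spec(loading_pattern = matrix(NA_real_, p, 1),
           n_endogenous = 0L, n_exogenous = 1L,
           phi_fixed = matrix(1, 1, 1))
}

#' Bundle parameter values of a specified SEM
#'
#' @param spec A [sem_spec()].
#' @param Lambda p x k loading matrix (fixed entries must match the pattern).
#' @param psi_eps Length-p vector of baseline measurement-error variances.
#'   For indicators flagged heteroscedastic this is the global
#'   \eqn{\sigma^2 = 1/h}; their realised variance is `psi_eps[k] * m(z_i)`.
#' @param Psi_delta Length-q1 vector of structural residual variances.
#' @param Phi q2 x q2 exogenous factor covariance.
#' @param Pi,Gamma Structural coefficient matrices (values; fixed entries per
#'   the pattern).
#' @param law A [variance_law()] carrying the heteroscedastic coefficients;
#'   its `scale` is kept in sync with the heteroscedastic `psi_eps` entries.
#' @return Object of class `model_parameters`.
#' @export
model_parameters <- function(spec, Lambda, psi_eps, Psi_delta = numeric(0),
                             Phi = NULL, Pi = NULL, Gamma = NULL,
                             law = variance_law("linear")) {
  stopifnot(inherits(spec, "sem_spec"))
  Lambda <- as.matrix(Lambda)
  stopifnot(dim(Lambda) == c(spec$p, spec$k))
  fx <- !is.na(spec$loading_pattern)
  if (any(abs(Lambda[fx] - spec$loading_pattern[fx]) > 1e-12)) {
    stop("Lambda disagrees with the fixed entries of the loading pattern")
  }
  psi_eps <- as.numeric(psi_eps)
  stopifnot(length(psi_eps) == spec$p)
  if (any(psi_eps <= 0)) stop("psi_eps entries must be strictly positive")
  if (spec$q1 > 0) {
    stopifnot(length(Psi_delta) == spec$q1)
    if (any(Psi_delta < 0)) stop("Psi_delta entries must be non-negative")
    if (is.null(Pi)) Pi <- ifelse(is.na(spec$Pi), 0, spec$Pi)
    if (is.null(Gamma)) Gamma <- ifelse(is.na(spec$Gamma), 0, spec$Gamma)
    Pi <- as.matrix(Pi); Gamma <- as.matrix(Gamma)
  } else {
    Pi <- spec$Pi; Gamma <- spec$Gamma
  }
  if (is.null(Phi)) {
    if (is.null(spec$phi_fixed)) stop("Phi must be supplied when not fixed")
    Phi <- spec$phi_fixed
  }
  Phi <- as.matrix(Phi)
  stopifnot(dim(Phi) == c(spec$q2, spec$q2))
  if (!isSymmetric(unname(Phi), tol = 1e-8)) stop("Phi must be symmetric")
  if (any(eigen((Phi + t(Phi)) / 2, symmetric = TRUE,
                only.values = TRUE)$values <= 0)) {
    stop("Phi must be positive definite")
  }
  structure(list(spec = spec, Lambda = Lambda, psi_eps = psi_eps,
                 Psi_delta = as.numeric(Psi_delta), Phi = Phi,
                 Pi = Pi, Gamma = Gamma, law = law),
            class = "model_parameters")
}

#' Model-implied covariance of the latent vector
#'
#' For \eqn{\omega = (\eta, \xi)} with \eqn{\Pi_0 = I - \Pi}:
#' top-left block \eqn{\Pi_0^{-1}(\Gamma \Phi \Gamma^T + \Psi_\delta)
#' \Pi_0^{-T}}, top-right \eqn{\Pi_0^{-1} \Gamma \Phi}, bottom-right
#' \eqn{\Phi}.  With no endogenous variables this is just \eqn{\Phi}.
#'
#' @param spec A [sem_spec()].
#' @param params A [model_parameters()].
#' @return Symmetric positive semi-definite (q1+q2) x (q1+q2) matrix.
#' @export
implied_latent_covariance <- function(spec, params) {
  q1 <- spec$q1; q2 <- spec$q2
  Phi <- params$Phi
  if (q1 == 0L) return((Phi + t(Phi)) / 2)
  Pi0 <- diag(q1) - params$Pi
  Pi0_inv <- tryCatch(solve(Pi0), error = function(e) {
    stop("non-recursive structural loop: I - Pi is singular")
  })
  if (!all(is.finite(Pi0_inv)) || rcond(Pi0) < 1e-12) {
    stop("non-recursive structural loop: I - Pi is singular")
  }
  G <- params$Gamma
  GPhi <- G %*% Phi
  top_left <- Pi0_inv %*% (GPhi %*% t(G) + diag(params$Psi_delta, q1)) %*%
    t(Pi0_inv)
  top_right <- Pi0_inv %*% GPhi
  out <- rbind(cbind(top_left, top_right),
               cbind(t(top_right), Phi))
  (out + t(out)) / 2
}

#' Model-implied covariance of the observed indicators
#'
#' The homoscedastic-baseline implied covariance
#' \eqn{\Lambda \Sigma_\omega \Lambda^T + \Psi_\varepsilon}.  Used by the
#' likelihood and the posterior-predictive discrepancy (which replace the
#' diagonal with the per-observation heteroscedastic variances).
#'
#' @inheritParams implied_latent_covariance
#' @return Symmetric p x p matrix.
#' @export
implied_observed_covariance <- function(spec, params) {
  So <- implied_latent_covariance(spec, params)
  out <- params$Lambda %*% So %*% t(params$Lambda) +
    diag(params$psi_eps, spec$p)
  (out + t(out)) / 2
}
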