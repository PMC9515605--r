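#' Parametric heteroscedastic variance laws
#'
#' A `variance_law` describes how the per-observation error-variance
#' multiplier \eqn{m_i} depends on a strictly positive observed driver
#' covariate \eqn{z_i}.  Four canonical econometric forms are supported:
#'
#' \describe{
#'   \item{`double_log`}{Harvey's multiplicative form,
#'     \eqn{m(z) = \exp(\lambda_0 + \lambda_1 \log z)}.}
#'   \item{`linear`}{Breusch-Pagan linear form,
#'     \eqn{m(z) = \lambda_1 + \lambda_2 z}.}
#'   \item{`linear_inverse`}{linear in the reciprocal,
#'     \eqn{m(z) = \lambda_1 + \lambda_2 / z}.}
#'   \item{`linear_absolute`}{Glejser's absolute-value form, the variance
#'     being the square of a linear function of \eqn{|z|}:
#'     \eqn{m(z) = (\lambda_1 + \lambda_2 |z|)^2}.}
#' }
#'
#' The full error variance of observation \eqn{i} is `scale * m(z_i)`, with
#' `scale` \eqn{= \sigma^2} a global baseline variance (reciprocal of the
#' global precision \eqn{h}).  All four laws nest homoscedasticity: setting
#' the slope coefficient to zero (and the double-log exponent
#' \eqn{\lambda_1 = 0}) makes \eqn{m} constant.
#'
#' When a law is *estimated* its scale coefficient is held fixed
#' (\eqn{\lambda_0 = 0} for `double_log`, \eqn{\lambda_1 = 1} otherwise) so
#' that the split between \eqn{\sigma^2} and the multiplier is identified;
#' see [law_free_names()].
#'
#' @param form One of `"double_log"`, `"linear"`, `"linear_inverse"`,
#'   `"linear_absolute"`.
#' @param coeffs Named numeric vector of coefficients.  `double_log` uses
#'   `lambda0`, `lambda1`; the other forms use `lambda1`, `lambda2`.
#'   Missing entries default to the homoscedastic null with unit multiplier
#'   (`lambda0 = 0`, `lambda1 = 1` as appropriate, slope `0`).
#' @param scale Global baseline variance \eqn{\sigma^2 \ge 0}.
#' @param normalize When `TRUE` the multipliers are renormalised to mean 1
#'   over the driver vector they are evaluated on (the *sample-normalised*
#'   parameterisation used for fitted laws, which makes the global
#'   precision \eqn{h} the average error precision and removes the scale
#'   redundancy between \eqn{\sigma^2} and the law).
#' @return An object of class `variance_law`.
#' @examples
#' law <- variance_law("linear", c(lambda1 = 0.5, lambda2 = 0.5), scale = 1)
#' variance_profile(law, c(1, 2, 3))
#' @export
variance_law <- function(form = c("double_log", "linear", "linear_inverse",
                                  "linear_absolute"),
                         coeffs = NULL, scale = 1, normalize = FALSE) {
  form <- match.arg(form)
  default <- if (form == "double_log") {
    c(lambda0 = 0, lambda1 = 0)
  } else {
    c(lambda1 = 1, lambda2 = 0)
  }
  if (!is.null(coeffs)) {
    if (is.null(names(coeffs)) && length(coeffs) == length(default)) {
      names(coeffs) <- names(default)
    }
    bad <- setdiff(names(coeffs), names(default))
    if (length(bad)) {
      stop("unknown coefficient(s) for form '", form, "': ",
           paste(bad, collapse = ", "))
    }
    default[names(coeffs)] <- coeffs
  }
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale < 0) {
    stop("'scale' must be a single finite non-negative number")
  }
  structure(list(form = form, coeffs = default, scale = scale,
                 normalize = isTRUE(normalize)),
            class = "variance_law")
}

#' @export
print.variance_law <- function(x, ...) {
  cat("<variance_law> form:", x$form, "\n  coeffs:",
      paste(names(x$coeffs), signif(x$coeffs, 4), sep = "=", collapse = ", "),
      "\n  scale (sigma^2):", signif(x$scale, 4), "\n")
  invisible(x)
}

#' Names of the coefficients estimated for a law form
#'
#' The remaining coefficient is the law's scale and is held fixed during
#' estimation (`lambda0 = 0` for `double_log`, `lambda1 = 1` otherwise); the
#' global variance `scale` absorbs it.
#'
#' @param form Law form string.
#' @return Character vector of free coefficient names.
#' @export
law_free_names <- function(form) {
  if (form == "double_log") "lambda1" else "lambda2"
}

#' Evaluate the per-observation variance multipliers of a law
#'
#' Returns the vector \eqn{m(z_i)} (the paper-style \eqn{\lambda_i^*}
#' multipliers, *not* including the global `scale`).
#'
#' @param law A [variance_law()].
#' @param driver Numeric driver covariate \eqn{z}; must be strictly positive
#'   for the `double_log` and `linear_inverse` forms, finite everywhere.
#' @return Numeric vector of strictly positive multipliers.
#' @export
variance_profile <- function(law, driver) {
  stopifnot(inherits(law, "variance_law"))
  z <- as.numeric(driver)
  if (anyNA(z) || any(!is.finite(z))) stop("driver must be finite")
  cf <- law$coeffs
  if (law$form %in% c("double_log", "linear_inverse") && any(z <= 0)) {
    stop("driver must be strictly positive for the ", law$form, " form")
  }
  m <- switch(law$form,
    double_log      = exp(cf[["lambda0"]] + cf[["lambda1"]] * log(z)),
    linear          = cf[["lambda1"]] + cf[["lambda2"]] * z,
    linear_inverse  = cf[["lambda1"]] + cf[["lambda2"]] / z,
    linear_absolute = (cf[["lambda1"]] + cf[["lambda2"]] * abs(z))^2
  )
  bad <- which(!(m > 0) | !is.finite(m))
  if (length(bad)) {
    stop("inadmissible variance law: non-positive variance at observation ",
         bad[1L])
  }
  if (isTRUE(law$normalize)) m <- m / mean(m)
  m
}

#' Disturbance covariance matrix of the heteroscedastic errors
#'
#' Builds the diagonal disturbance covariance with entries
#' \eqn{\sigma^2 m(z_i)}: the global baseline variance times the law's
#' per-observation multiplier.  Off-diagonal entries are structurally zero
#' (errors independent across observations).
#'
#' @inheritParams variance_profile
#' @return An object of class `disturbance_cov`: list with `diagonal` (the
#'   n variances) and the generating `law`.
#' @export
build_omega <- function(law, driver) {
  m <- variance_profile(law, driver)
  structure(list(diagonal = law$scale * m, law = law),
            class = "disturbance_cov")
}

#' @export
print.disturbance_cov <- function(x, ...) {
  cat("<disturbance_cov> n =", length(x$diagonal),
      " range:", signif(min(x$diagonal), 4), "-",
      signif(max(x$diagonal), 4), "\n")
  invisible(x)
}

# Moments of the driver distribution needed for average-variance calibration.
# Only the uniform family is used by the shipped generator.
.driver_moments <- function(driver_spec) {
  stopifnot(driver_spec$dist == "uniform")
  a <- driver_spec$min; b <- driver_spec$max
  stopifnot(a > 0, b > a)
  list(
    mean     = (a + b) / 2,
    inv_mean = log(b / a) / (b - a),
    sq_mean  = (b^3 - a^3) / (3 * (b - a))
  )
}

#' Calibrated generating law for the simulation design
#'
#' Returns the `variance_law` used as generating truth: a fixed shape per
#' form, rescaled so the *average* error variance over the driver
#' distribution equals `1 / precision`.  This makes the single reported
#' precision comparable across all four forms.
#'
#' Shapes (before normalisation): `double_log` uses \eqn{s(z) = z};
#' `linear` \eqn{s(z) = 0.5 + z}; `linear_inverse` \eqn{s(z) = 0.5 + 1/z};
#' `linear_absolute` \eqn{s(z) = (0.5 + 0.5 z)^2}.
#'
#' @param form Law form string.
#' @param precision Target average precision (default 15).
#' @param driver_spec List describing the driver distribution; default
#'   `list(dist = "uniform", min = 0.5, max = 2)`.
#' @return A [variance_law()] with `scale = 1/precision` and coefficients
#'   normalised so the expected multiplier is 1.
#' @export
calibrated_law <- function(form, precision = 15,
                           driver_spec = list(dist = "uniform",
                                              min = 0.5, max = 2)) {
  mo <- .driver_moments(driver_spec)
  # E[s(z)] under the driver distribution, analytically
  Es <- switch(form,
    double_log      = mo$mean,
    linear          = 0.5 + mo$mean,
    linear_inverse  = 0.5 + mo$inv_mean,
    linear_absolute = 0.25 * (1 + 2 * mo$mean + mo$sq_mean)
  )
  if (is.null(Es)) stop("unknown form '", form, "'")
  coeffs <- switch(form,
    double_log      = c(lambda0 = -log(Es), lambda1 = 1),
    linear          = c(lambda1 = 0.5 / Es, lambda2 = 1 / Es),
    linear_inverse  = c(lambda1 = 0.5 / Es, lambda2 = 1 / Es),
    linear_absolute = c(lambda1 = 0.5 / sqrt(Es), lambda2 = 0.5 / sqrt(Es))
  )
  variance_law(form, coeffs, scale = 1 / precision)
}
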