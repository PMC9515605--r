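#' Configuration of the synthetic heteroscedastic factor-model generator
#'
#' The generator emulates the simulation design of the study: a single
#' standard-normal exogenous factor (\eqn{\Phi = 1} fixed for
#' identification) measured by indicators with true loadings
#' \eqn{(\lambda_1, \lambda_2) = (2, 3)}, measurement errors
#' \eqn{\varepsilon_{ik} \sim N(0, \sigma^2 m(z_i))} driven by a
#' Uniform(0.5, 2) covariate under one of the four variance laws, and the
#' law calibrated (see [calibrated_law()]) so the average error variance is
#' `1 / precision` with `precision = 15`.
#'
#' @param n Sample size (>= 2).
#' @param loadings True loadings; length gives the number of indicators.
#' @param precision True average error precision (> 0).
#' @param form Variance-law form.
#' @param law Optional [variance_law()] overriding the calibrated default.
#' @param driver_spec Driver distribution, `list(dist = "uniform", min, max)`.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n, loadings = c(2, 3), precision = 15,
                              form = c("linear", "double_log",
                                       "linear_inverse", "linear_absolute"),
                              law = NULL,
                              driver_spec = list(dist = "uniform",
                                                 min = 0.5, max = 2),
                              seed = 1L) {
  form <- match.arg(form)
  stopifnot(n >= 2, precision > 0, length(loadings) >= 1)
  if (is.null(law)) law <- calibrated_law(form, precision, driver_spec)
  stopifnot(inherits(law, "variance_law"), law$form == form)
  structure(list(n = as.integer(n), loadings = as.numeric(loadings),
                 precision = precision, form = form, law = law,
                 driver_spec = driver_spec, seed = as.integer(seed)),
            class = "simulation_config")
}

.draw_driver <- function(driver_spec, n) {
  stopifnot(driver_spec$dist == "uniform")
  stats::runif(n, driver_spec$min, driver_spec$max)
}

#' Simulate a dataset from the heteroscedastic one-factor model
#'
#' Draws \eqn{\xi_i \sim N(0,1)}, a driver \eqn{z_i}, measurement errors
#' with variances `law$scale * m(z_i)` identical across indicators, and
#' \eqn{y_i = \Lambda \xi_i + \varepsilon_i}.  The generating truth
#' (including the realised latent scores) travels with the dataset for
#' recovery checks.
#'
#' @param config A [simulation_config()].
#' @return Object of class `sem_dataset`: list with `y` (n x p matrix,
#'   columns `y1..yp`), `z` (driver), `latent` (true scores) and `truth`
#'   (the config).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n
  p <- length(config$loadings)
  z <- .draw_driver(config$driver_spec, n)
  v <- config$law$scale * variance_profile(config$law, z)
  xi <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * p, sd = sqrt(v)), n, p)
  y <- outer(xi, config$loadings) + eps
  colnames(y) <- paste0("y", seq_len(p))
  structure(list(y = y, z = z, latent = xi, truth = config),
            class = "sem_dataset")
}

#' @export
print.sem_dataset <- function(x, ...) {
  cat("<sem_dataset> n =", nrow(x$y), " p =", ncol(x$y),
      if (!is.null(x$truth)) paste0(" (simulated, ", x$truth$form, " law)"),
      "\n")
  invisible(x)
}

#' Zero-mean heteroscedastic normal noise
#'
#' Independent normal draws with per-observation variances
#' `law$scale * variance_profile(law, driver)`.  A zero `scale` yields an
#' all-zero vector.
#'
#' @param law A [variance_law()].
#' @param driver Driver covariate.
#' @param seed Optional integer seed (two calls with the same seed return
#'   identical vectors).
#' @return Numeric vector, `length(driver)`.
#' @export
heteroscedastic_noise <- function(law, driver, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- law$scale * variance_profile(law, driver)
  stats::rnorm(length(driver), sd = sqrt(v))
}

#' Assemble a dataset from raw components
#'
#' @param y n x p numeric matrix or data frame of indicators.
#' @param z Length-n positive driver covariate.
#' @return A `sem_dataset`.
#' @export
sem_dataset <- function(y, z) {
  y <- as.matrix(y)
  stopifnot(nrow(y) == length(z), !anyNA(y), !anyNA(z))
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(ncol(y)))
  structure(list(y = y, z = as.numeric(z), latent = NULL, truth = NULL),
            class = "sem_dataset")
}
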