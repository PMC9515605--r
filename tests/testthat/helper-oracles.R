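# Independent oracles used by the test suite.  These deliberately re-derive
# quantities from first principles (grid integration, direct density
# summation, brute-force simulation) without touching the package's
# sampling code paths.

# trapezoid-normalised grid distribution from an unnormalised log density
grid_dist <- function(grid, logf) {
  logf <- logf - max(logf)
  w <- exp(logf)
  dx <- diff(grid)
  cell <- c(0, (w[-1] + w[-length(w)]) / 2 * dx)
  cdf <- cumsum(cell)
  list(grid = grid, pdf = w / cdf[length(cdf)], cdf = cdf / cdf[length(cdf)],
       mean = sum(grid * cell) / cdf[length(cdf)],
       var = sum(grid^2 * cell) / cdf[length(cdf)] -
         (sum(grid * cell) / cdf[length(cdf)])^2)
}

# Kolmogorov distance between draws and a grid CDF
ks_grid <- function(draws, gd) {
  ec <- stats::ecdf(draws)
  max(abs(ec(gd$grid) - gd$cdf))
}

# unnormalised log conditional of a scalar loading:
# y | lambda ~ N(lambda * x, m / h), prior lambda ~ N(l0, 1/H0)
loading_logpost <- function(lambda_grid, y, x, m, h, l0, H0) {
  vapply(lambda_grid, function(l) {
    -0.5 * h * sum((y - l * x)^2 / m) - 0.5 * H0 * (l - l0)^2
  }, 1)
}

# unnormalised log conditional of the free variance-law coefficient
varlaw_logpost_oracle <- function(theta_grid, form, z, sq_resid, ph, h,
                                  pm, psd) {
  mfun <- switch(form,
    double_log      = function(th) z^th,
    linear          = function(th) 1 + th * z,
    linear_inverse  = function(th) 1 + th / z,
    linear_absolute = function(th) (1 + th * abs(z))^2)
  vapply(theta_grid, function(th) {
    m <- mfun(th)
    if (any(m <= 0)) return(-Inf)
    -0.5 * ph * sum(log(m)) - 0.5 * h * sum(sq_resid / m) +
      stats::dnorm(th, pm, psd, log = TRUE)
  }, 1)
}

# direct per-observation multivariate normal log density via solve()
mvn_loglik_oracle <- function(y, B, V) {
  n <- nrow(y); p <- ncol(y)
  ll <- 0
  for (i in seq_len(n)) {
    Ci <- B + diag(V[i, ], p)
    ll <- ll + as.numeric(
      -0.5 * p * log(2 * pi) - 0.5 * log(det(Ci)) -
        0.5 * t(y[i, ]) %*% solve(Ci) %*% y[i, ])
  }
  ll
}

# type-7 quantile re-derived by explicit sorting and interpolation
sort_quantile_oracle <- function(x, probs) {
  xs <- sort(x)
  n <- length(xs)
  vapply(probs, function(p) {
    hh <- (n - 1) * p + 1
    lo <- floor(hh)
    xs[lo] + (hh - lo) * (xs[min(lo + 1, n)] - xs[lo])
  }, 1)
}

# Monte-Carlo standard error of a covariance entry of a normal sample
cov_mc_se <- function(Sig, i, j, N) {
  sqrt((Sig[i, i] * Sig[j, j] + Sig[i, j]^2) / N)
}

# a small fitted run used by several tests
quick_fit <- function(n = 100, form = "linear", seed = 1, S = 1500,
                      S0 = 500, ...) {
  d <- simulate_dataset(simulation_config(n = n, form = form, seed = seed))
  fit <- run_gibbs(d, config = sampler_config(S, S0, n_chains = 1L,
                                              seed = seed, ...))
  list(data = d, fit = fit, summary = summarize_chains(fit))
}

pm_of <- function(summ, par) summ$PM[summ$parameter == par]
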