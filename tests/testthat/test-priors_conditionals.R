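# one-draw full conditionals against closed forms and grid oracles

test_that("loading draw collapses to the prior under infinite precision", {
  set.seed(11)
  x <- rnorm(40); y <- 2 * x + rnorm(40)
  d <- replicate(20, draw_loading_row(y, cbind(x), precision = 1,
                                      omega = rep(1, 40),
                                      prior_mean = 5,
                                      prior_precision = 1e12))
  expect_true(all(abs(d - 5) < 1e-5))
})

test_that("loading draw collapses to OLS under a flat prior", {
  set.seed(12)
  x <- rnorm(60); y <- 1.5 * x + rnorm(60)
  ols <- sum(x * y) / sum(x^2)
  nd <- 2e4
  d <- replicate(nd, draw_loading_row(y, cbind(x), precision = 1,
                                      omega = rep(1, 60),
                                      prior_mean = 0,
                                      prior_precision = 1e-12))
  post_sd <- 1 / sqrt(sum(x^2))
  expect_lt(abs(mean(d) - ols), 4 * post_sd / sqrt(nd))
  expect_lt(abs(sd(d) - post_sd), 4 * post_sd / sqrt(nd))
})

test_that("scalar loading draw matches the grid-integration oracle", {
  set.seed(13)
  n <- 25
  x <- rnorm(n); m <- runif(n, 0.5, 2); h <- 12
  y <- 2 * x + rnorm(n, sd = sqrt(m / h))
  grid <- seq(0, 4, length.out = 4001)
  gd <- grid_dist(grid, loading_logpost(grid, y, x, m, h, l0 = 2, H0 = 1))
  nd <- 5e4
  d <- replicate(nd, draw_loading_row(y, cbind(x), h, m, 2, 1))
  expect_lt(abs(mean(d) - gd$mean), 3 * sd(d) / sqrt(nd))
  expect_lt(ks_grid(d, gd), 0.02)
})

test_that("precision draw: prior regime, zero residuals, consistency", {
  set.seed(14)
  # n = 0: prior draws, mean alpha0 / beta0
  d0 <- replicate(1e5, draw_precision(numeric(0), numeric(0), 9, 0.6))
  expect_lt(abs(mean(d0) - 15), 4 * (sqrt(9) / 0.6) / sqrt(1e5))
  # zero residuals: Gamma(alpha0 + n/2, beta0) exactly
  dz <- replicate(2e4, draw_precision(rep(0, 10), rep(1, 10), 2, 3))
  expect_lt(abs(mean(dz) - 7 / 3), 4 * (sqrt(7) / 3) / sqrt(2e4))
  # consistency: known precision 15, diffuse prior
  n <- 1e4
  r <- rnorm(n, sd = sqrt(1 / 15))
  post_mean <- (0.01 + n / 2) / (0.01 + 0.5 * sum(r^2))
  expect_lt(abs(post_mean - 15) / 15, 0.02)
  dh <- replicate(5e3, draw_precision(r, rep(1, n), 0.01, 0.01))
  expect_lt(abs(mean(dh) - post_mean) / post_mean, 0.02)
})

test_that("factor covariance draw has the inverse-Wishart prior mean", {
  set.seed(15)
  v0 <- 7; V0 <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  prior_mean <- V0 / (v0 - 2 - 1)
  draws <- replicate(1e5, draw_factor_cov(matrix(0, 0, 2), v0, V0))
  emp <- apply(draws, c(1, 2), mean)
  emp_se <- apply(draws, c(1, 2), sd) / sqrt(1e5)
  expect_true(all(abs(emp - prior_mean) < 4 * emp_se))
})

test_that("q2 = 1 factor covariance reduces to inverse gamma", {
  set.seed(16)
  v0 <- 10; V0 <- matrix(2, 1, 1)
  d <- replicate(5e4, draw_factor_cov(matrix(0, 0, 1), v0, V0)[1, 1])
  # IW(v0, V0) in 1-d is InvGamma(v0/2, V0/2)
  a <- v0 / 2; b <- V0[1, 1] / 2
  expect_lt(abs(mean(d) - b / (a - 1)), 0.01)
  expect_lt(abs(var(d) - b^2 / ((a - 1)^2 * (a - 2))) /
              (b^2 / ((a - 1)^2 * (a - 2))), 0.1)
})

test_that("factor covariance concentrates at the truth with data", {
  set.seed(17)
  Phi <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  X <- matrix(rnorm(2 * 5000), 5000, 2) %*% chol(Phi)
  d <- replicate(2000, draw_factor_cov(X, 3, diag(2) * 0.01))
  emp <- apply(d, c(1, 2), mean)
  S_emp <- crossprod(X) / 5000   # the draw concentrates at the sample SS
  expect_true(all(abs(emp - S_emp) / S_emp < 0.05))
})

test_that("latent score draws honour the degenerate limits", {
  set.seed(18)
  # noise-free identity loadings: scores reproduce the data
  sp <- sem_spec(matrix(c(1, 0, 0, 1), 2, 2), n_exogenous = 2L,
                 phi_fixed = diag(2),
                 heteroscedastic = c(FALSE, FALSE)) |> suppressWarnings()
  pm <- model_parameters(sp, Lambda = diag(2), psi_eps = rep(1e-12, 2),
                         Phi = diag(2))
  y <- matrix(rnorm(20), 10, 2)
  w <- draw_latent_scores(y, pm)
  expect_lt(max(abs(w - y)), 1e-3)
  # zero loadings: draws from the prior N(0, Sigma_omega)
  sp0 <- two_indicator_spec()
  pm0 <- model_parameters(sp0, Lambda = matrix(0, 2, 1),
                          psi_eps = c(1, 1),
                          law = variance_law("linear", c(1, 0), scale = 1))
  y0 <- matrix(rnorm(2 * 4e4, sd = 3), ncol = 2)
  w0 <- draw_latent_scores(y0, pm0, driver = runif(4e4, 0.5, 2))
  expect_lt(abs(mean(w0)), 4 / sqrt(4e4))
  expect_lt(abs(var(as.vector(w0)) - 1), 4 * sqrt(2 / 4e4))
})

test_that("latent score conditional matches the grid oracle", {
  set.seed(19)
  sp <- two_indicator_spec()
  law <- variance_law("linear", c(1, 0.5), scale = 1)
  pm <- model_parameters(sp, Lambda = matrix(c(2, 3), 2, 1),
                         psi_eps = c(0.2, 0.2), law = law)
  yrow <- c(1.4, 2.9); z1 <- 1.2
  m1 <- variance_profile(law, z1)
  v <- 0.2 * m1
  grid <- seq(-3, 4, length.out = 4001)
  logf <- dnorm(grid, log = TRUE) +
    dnorm(yrow[1], 2 * grid, sqrt(v), log = TRUE) +
    dnorm(yrow[2], 3 * grid, sqrt(v), log = TRUE)
  gd <- grid_dist(grid, logf)
  nrep <- 5e4
  Y <- matrix(rep(yrow, each = nrep), nrep, 2)
  w <- draw_latent_scores(Y, pm, driver = rep(z1, nrep))
  expect_lt(abs(mean(w) - gd$mean), 3 * sd(w) / sqrt(nrep))
  expect_lt(abs(var(as.vector(w)) - gd$var) / gd$var, 0.05)
  expect_lt(ks_grid(as.vector(w), gd), 0.02)
})

test_that("zero proposal scale leaves the variance-law chain in place", {
  set.seed(20)
  e <- rnorm(30, sd = 0.3)
  cur <- 0.4
  for (i in 1:50) {
    st <- draw_varlaw_coeffs(e, runif(30, 0.5, 2), "linear", cur,
                             precision = 10, proposal_scale = 0)
    expect_true(st$accepted)
    expect_identical(st$coeffs, cur)
  }
})

test_that("homoscedastic truth keeps the slope's interval around zero", {
  set.seed(21)
  n <- 400
  z <- runif(n, 0.5, 2)
  h <- 15
  e <- rnorm(n, sd = sqrt(1 / h))   # true slope 0
  th <- 0; draws <- numeric(2e4)
  for (i in seq_along(draws)) {
    st <- draw_varlaw_coeffs(e, z, "linear", th, h, prior_mean = 0,
                             prior_sd = 2, proposal_scale = 0.3)
    th <- st$coeffs; draws[i] <- th
  }
  ci <- quantile(draws[-(1:2000)], c(0.025, 0.975))
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
})

test_that("Metropolis chain reproduces the grid conditional density", {
  set.seed(22)
  n <- 120
  z <- runif(n, 0.5, 2)
  h <- 15
  true_m <- 1 + 1.5 * z
  e <- rnorm(n, sd = sqrt(true_m / h))
  nd <- 5e4
  th <- 0; draws <- numeric(nd)
  for (i in seq_len(nd)) {
    st <- draw_varlaw_coeffs(e, z, "linear", th, h, prior_mean = 0,
                             prior_sd = 2, proposal_scale = 0.8)
    th <- st$coeffs; draws[i] <- th
  }
  grid <- seq(-0.65, 8, length.out = 3001)
  gd <- grid_dist(grid, varlaw_logpost_oracle(grid, "linear", z, e^2, 1,
                                              h, 0, 2))
  expect_lt(ks_grid(draws, gd), 0.02)
})

test_that("prior constructors validate their hyperparameters", {
  sp <- two_indicator_spec()
  expect_error(prior_spec(sp, lambda0 = c(2, 3), varlaw_sd = -1))
  expect_error(prior_spec(sp, lambda0 = c(2, 3), alpha0_eps = c(-1, 1)))
  expect_s3_class(prior_preset(sp, "informative"), "prior_spec")
  expect_false(prior_preset(sp, "diffuse")$informative)
  expect_equal(prior_preset(sp, "informative")$lambda0, matrix(c(2, 3), 2, 1))
})
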