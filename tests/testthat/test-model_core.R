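# model skeleton, implied covariances, and the four variance laws

spec_1f1e <- function(Pi = matrix(0, 1, 1), Gamma = matrix(1, 1, 1),
                      phi = matrix(1, 1, 1)) {
  sem_spec(loading_pattern = matrix(c(1, 0, 0, 1), 2, 2),
           n_endogenous = 1L, n_exogenous = 1L,
           Pi = Pi, Gamma = Gamma, phi_fixed = phi)
}

test_that("implied latent covariance reproduces the block formula", {
  sp <- spec_1f1e()
  pm <- model_parameters(sp, Lambda = matrix(c(1, 0, 0, 1), 2, 2),
                         psi_eps = c(1, 1), Psi_delta = 0,
                         Phi = matrix(1, 1, 1))
  expect_equal(implied_latent_covariance(sp, pm),
               matrix(1, 2, 2))

  sp2 <- spec_1f1e(Gamma = matrix(0, 1, 1), phi = matrix(2, 1, 1))
  pm2 <- model_parameters(sp2, Lambda = matrix(c(1, 0, 0, 1), 2, 2),
                          psi_eps = c(1, 1), Psi_delta = 3,
                          Phi = matrix(2, 1, 1))
  expect_equal(implied_latent_covariance(sp2, pm2),
               diag(c(3, 2)))
})

test_that("implied latent covariance matches a brute-force simulation", {
  # eta = (I - Pi)^-1 (Gamma xi + delta), random admissible coefficients
  set.seed(71)
  Pi <- matrix(c(0, 0.4, 0.2, 0), 2, 2)
  Gamma <- matrix(c(0.8, -0.5, 0.3, 0.9), 2, 2)
  Phi <- matrix(c(1, 0.3, 0.3, 1.5), 2, 2)
  psd <- c(0.5, 0.8)
  sp <- sem_spec(loading_pattern = matrix(1, 4, 4), n_endogenous = 2L,
                 n_exogenous = 2L, Pi = Pi, Gamma = Gamma, phi_fixed = Phi)
  pm <- model_parameters(sp, Lambda = matrix(1, 4, 4), psi_eps = rep(1, 4),
                         Psi_delta = psd, Phi = Phi, Pi = Pi, Gamma = Gamma)
  Sig <- implied_latent_covariance(sp, pm)
  expect_true(isSymmetric(Sig))
  expect_true(all(eigen(Sig, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))

  N <- 1e6
  Rphi <- chol(Phi)
  xi <- matrix(rnorm(2 * N), N, 2) %*% Rphi
  delta <- cbind(rnorm(N, sd = sqrt(psd[1])), rnorm(N, sd = sqrt(psd[2])))
  eta <- t(solve(diag(2) - Pi, t(xi %*% t(Gamma) + delta)))
  emp <- cov(cbind(eta, xi))
  for (i in 1:4) for (j in 1:4) {
    expect_lt(abs(emp[i, j] - Sig[i, j]), 4 * cov_mc_se(Sig, i, j, N))
  }
})

test_that("singular I - Pi raises a structural-loop error", {
  sp <- sem_spec(loading_pattern = matrix(1, 4, 4), n_endogenous = 2L,
                 n_exogenous = 2L, Pi = matrix(c(0, 1, 1, 0), 2, 2),
                 Gamma = matrix(0, 2, 2), phi_fixed = diag(2))
  pm <- model_parameters(sp, Lambda = matrix(1, 4, 4), psi_eps = rep(1, 4),
                         Psi_delta = c(1, 1), Phi = diag(2),
                         Pi = matrix(c(0, 1, 1, 0), 2, 2),
                         Gamma = matrix(0, 2, 2))
  expect_error(implied_latent_covariance(sp, pm), "non-recursive")
})

test_that("implied observed covariance matches arithmetic and simulation", {
  sp <- sem_spec(matrix(c(2, 3), 2, 1), phi_fixed = matrix(1, 1, 1))
  pm <- model_parameters(sp, Lambda = matrix(c(2, 3), 2, 1),
                         psi_eps = c(1 / 15, 1 / 15))
  S <- implied_observed_covariance(sp, pm)
  expect_equal(S, matrix(c(4 + 1 / 15, 6, 6, 9 + 1 / 15), 2, 2))

  pm0 <- model_parameters(sem_spec(matrix(c(0, 0), 2, 1),
                                   phi_fixed = matrix(1, 1, 1)),
                          Lambda = matrix(0, 2, 1), psi_eps = c(0.2, 0.7))
  expect_equal(implied_observed_covariance(pm0$spec, pm0),
               diag(c(0.2, 0.7)))

  set.seed(5)
  N <- 1e6
  y <- outer(rnorm(N), c(2, 3)) +
    cbind(rnorm(N, sd = sqrt(1 / 15)), rnorm(N, sd = sqrt(1 / 15)))
  emp <- cov(y)
  for (i in 1:2) for (j in 1:2) {
    expect_lt(abs(emp[i, j] - S[i, j]), 4 * cov_mc_se(S, i, j, N))
  }
})

test_that("variance profiles evaluate the four canonical forms", {
  z <- c(0.7, 1.3, 1.9)
  expect_equal(variance_profile(variance_law("linear", c(1, 0)), z),
               rep(1, 3))
  expect_equal(variance_profile(variance_law("double_log", c(0, 1)),
                                exp(1)), exp(1))
  expect_equal(variance_profile(variance_law("linear_inverse", c(1, 2)), 4),
               1.5)
  expect_equal(variance_profile(variance_law("linear_absolute",
                                             c(0.5, 0.25)), 2),
               1)
})

test_that("inadmissible profiles and drivers raise informative errors", {
  law <- variance_law("linear", c(lambda1 = 1, lambda2 = -1))
  expect_error(variance_profile(law, c(0.5, 2)), "observation 2")
  expect_error(variance_profile(variance_law("double_log"), c(1, -1)),
               "strictly positive")
  expect_error(variance_profile(variance_law("linear_inverse"), c(0, 1)),
               "strictly positive")
  expect_error(variance_law("linear", c(lambda0 = 1)), "unknown coefficient")
})

test_that("build_omega assembles the diagonal disturbance covariance", {
  law <- variance_law("linear", c(1, 0), scale = 1 / 15)
  om <- build_omega(law, runif(5, 0.5, 2))
  expect_equal(om$diagonal, rep(1 / 15, 5))

  law2 <- variance_law("linear", c(0.5, 0.5), scale = 1 / 15)
  om2 <- build_omega(law2, c(1, 2, 3))
  expect_equal(om2$diagonal, c(1, 1.5, 2) / 15)
  # diagonal-matrix determinant identity
  expect_equal(prod(om2$diagonal), det(diag(om2$diagonal)))
})

test_that("all four laws nest homoscedasticity at zero slope", {
  set.seed(2)
  for (r in 1:5) {
    z <- runif(20, 0.3, 3)
    expect_equal(variance_profile(variance_law("linear", c(1.7, 0)), z),
                 rep(1.7, 20))
    expect_equal(variance_profile(variance_law("linear_inverse",
                                               c(1.7, 0)), z),
                 rep(1.7, 20))
    expect_equal(variance_profile(variance_law("double_log",
                                               c(log(1.7), 0)), z),
                 rep(1.7, 20))
    expect_equal(variance_profile(variance_law("linear_absolute",
                                               c(sqrt(1.7), 0)), z),
                 rep(1.7, 20))
  }
})

test_that("calibrated generating laws average to the target variance", {
  set.seed(3)
  z <- runif(2e5, 0.5, 2)
  for (f in c("double_log", "linear", "linear_inverse", "linear_absolute")) {
    law <- calibrated_law(f, precision = 15)
    v <- law$scale * variance_profile(law, z)
    expect_lt(abs(mean(v) - 1 / 15) / (1 / 15), 0.01)
  }
})

test_that("unidentified specs are rejected, anchored ones accepted", {
  expect_error(sem_spec(matrix(NA_real_, 2, 1)), "unidentified")
  expect_s3_class(sem_spec(matrix(c(1, NA), 2, 1)), "sem_spec")
  expect_s3_class(two_indicator_spec(), "sem_spec")
})
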