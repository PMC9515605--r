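Package: hetsem
Title: Bayesian Structural Equation Models with Heteroscedastic Errors
Version: 0.1.0
Authors@R:
    person("hetsem", "maintainers", email = "hetsem@example.org",
           role = c("aut", "cre"))
Description: Gibbs sampling for structural equation models whose
    measurement-error variance varies across observations according to one
    of four parametric heteroscedastic variance laws (Harvey multiplicative,
    Breusch-Pagan linear, linear-inverse, and Glejser absolute forms) driven
    by an observed positive covariate.  Conjugate normal-gamma-inverse-Wishart
    priors yield closed-form full conditionals for loadings, precisions,
    latent scores and factor covariances; the variance-law coefficients are
    updated by a random-walk Metropolis step.  Includes posterior-predictive
    model checking, convergence diagnostics, a synthetic-data generator for
    heteroscedastic factor models, a simulation-grid harness, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
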