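#' Sampler configuration
#'
#' @param n_iterations Total Gibbs sweeps S per chain.
#' @param burn_in Initial sweeps S0 dropped (S > S0 >= 0; equality would
#'   leave no retained draws and is rejected).
#' @param n_chains Number of independent chains (>= 1).
#' @param seed Root integer seed; per-chain seeds are derived from it by
#'   fixed offsets, so runs are reproducible bit-for-bit.
#' @param thin Keep every `thin`-th post-burn-in draw (>= 1).
#' @param store_latent Also store the latent-score draws (memory-hungry).
#' @param proposal_scale Random-walk sd of the variance-law Metropolis step.
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(n_iterations = 10000L, burn_in = 2000L,
                           n_chains = 2L, seed = 1L, thin = 1L,
                           store_latent = FALSE, proposal_scale = 0.1) {
  S <- as.integer(n_iterations); S0 <- as.integer(burn_in)
  if (S0 < 0L) stop("burn_in must be non-negative")
  if (S <= S0) stop("no retained draws: n_iterations must exceed burn_in")
  if (as.integer(thin) < 1L) stop("thin must be >= 1")
  if (as.integer(n_chains) < 1L) stop("n_chains must be >= 1")
  structure(list(n_iterations = S, burn_in = S0,
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 thin = as.integer(thin), store_latent = isTRUE(store_latent),
                 proposal_scale = proposal_scale),
            class = "sampler_config")
}

.chain_seed <- function(root, chain) {
  as.integer((as.numeric(root) * 97 + 1009 * chain) %% (2^31 - 1))
}

# shared low-level score draw; V is the n x p matrix of error variances
.draw_scores_raw <- function(y, V, L, sigma_omega) {
  n <- nrow(y); k <- ncol(L)
  if (k == 1L) {
    prec <- 1 / sigma_omega[1, 1] + as.vector((1 / V) %*% L[, 1]^2)
    mu <- as.vector((y / V) %*% L[, 1]) / prec
    return(matrix(mu + stats::rnorm(n) / sqrt(prec), ncol = 1L))
  }
  out <- matrix(0, n, k)
  B <- L %*% sigma_omega
  for (i in seq_len(n)) {
    Ci <- tcrossprod(B, L)
    diag(Ci) <- diag(Ci) + V[i, ]
    CiB <- solve(Ci, B)
    mu <- drop(crossprod(CiB, y[i, ]))
    Vc <- sigma_omega - crossprod(B, CiB)
    Vc <- (Vc + t(Vc)) / 2
    R <- tryCatch(chol(Vc), error = function(e) {
      tryCatch(chol(Vc + diag(1e-8, k)), error = function(e2) {
        stop("conditional score covariance not positive definite")
      })
    })
    out[i, ] <- mu + drop(t(R) %*% stats::rnorm(k))
  }
  out
}

#' Run the Gibbs sampler for the heteroscedastic SEM
#'
#' Each chain is initialised deterministically (loadings and precisions at
#' their prior means, \eqn{\Phi} at its prior mean or fixed value, the
#' variance-law coefficient at the homoscedastic null, latent scores at
#' zero) and then swept in fixed block order: latent scores; loading rows
#' with the measurement precisions (one pooled global precision \eqn{h} for
#' the heteroscedastic indicators, individual precisions otherwise);
#' structural rows with their residual precisions; \eqn{\Phi} (when free);
#' and a Metropolis update of the variance-law coefficient.  The first
#' `burn_in` sweeps are dropped.  Runs are deterministic given
#' `(seed, config, data)`.
#'
#' @param data A `sem_dataset` (see [simulate_dataset()] / [sem_dataset()]).
#' @param spec A [sem_spec()]; defaults to the two-indicator fixture sized
#'   to the data.
#' @param priors A [prior_spec()]; defaults to the informative preset.
#' @param form Variance-law form fitted to the heteroscedastic indicators.
#' @param config A [sampler_config()].
#' @return Object of class `sem_chains` with one draw matrix per chain
#'   (columns named per scalar parameter), Metropolis acceptance rates, and
#'   provenance (seed, config, spec, priors, form).
#' @examples
#' d <- simulate_dataset(simulation_config(n = 60, seed = 1))
#' fit <- run_gibbs(d, config = sampler_config(500, 100, n_chains = 1))
#' summarize_chains(fit)[, 1:3]
#' @export
run_gibbs <- function(data, spec = NULL, priors = NULL,
                      form = if (!is.null(data$truth)) data$truth$form
                             else "linear",
                      config = sampler_config()) {
  stopifnot(inherits(data, "sem_dataset"), inherits(config, "sampler_config"))
  y <- data$y; z <- data$z
  n <- nrow(y); p <- ncol(y)
  if (is.null(spec)) spec <- two_indicator_spec(p)
  if (spec$p != p) stop("data has ", p, " indicators but spec expects ",
                        spec$p)
  if (is.null(priors)) priors <- prior_preset(spec, "informative")
  q1 <- spec$q1; q2 <- spec$q2; k <- spec$k
  het <- spec$heteroscedastic
  kh <- which(het); nh <- which(!het)
  use_law <- length(kh) > 0L
  free_name <- law_free_names(form)

  pat <- spec$loading_pattern
  free_rows <- lapply(seq_len(p), function(i) which(is.na(pat[i, ])))
  phi_free <- is.null(spec$phi_fixed)

  # --- column layout ------------------------------------------------------
  lam_names <- unlist(lapply(seq_len(p), function(i) {
    if (!length(free_rows[[i]])) return(character(0))
    if (k == 1L) paste0("lambda", i) else
      paste0("lambda[", i, ",", free_rows[[i]], "]")
  }))
  cn <- lam_names
  if (use_law) cn <- c(cn, "precision", paste0("varlaw_", free_name))
  if (length(nh)) cn <- c(cn, paste0("psi_eps", nh))
  cn <- c(cn, paste0("errvar", seq_len(p)))
  if (q1 > 0) {
    st_names <- character(0)
    for (l in seq_len(q1)) {
      fp <- which(is.na(spec$Pi[l, ]))
      fg <- which(is.na(spec$Gamma[l, ]))
      st_names <- c(st_names,
                    if (length(fp)) paste0("pi[", l, ",", fp, "]"),
                    if (length(fg)) paste0("gamma[", l, ",", fg, "]"),
                    paste0("psi_delta", l))
    }
    cn <- c(cn, st_names)
  }
  if (phi_free) {
    ut <- which(upper.tri(diag(q2), diag = TRUE), arr.ind = TRUE)
    cn <- c(cn, paste0("phi[", ut[, 1], ",", ut[, 2], "]"))
  }

  S <- config$n_iterations; S0 <- config$burn_in; thin <- config$thin
  nstore <- (S - S0) %/% thin
  alpha_h <- priors$alpha0_eps[if (use_law) kh[1] else 1L]
  beta_h <- priors$beta0_eps[if (use_law) kh[1] else 1L]

  chains <- vector("list", config$n_chains)
  latent <- if (config$store_latent) vector("list", config$n_chains)
  acc_rates <- numeric(config$n_chains)
  chain_seeds <- vapply(seq_len(config$n_chains),
                        function(ch) .chain_seed(config$seed, ch), 1L)

  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    # --- initialisation (deterministic, prior-consistent) -----------------
    Lambda <- ifelse(is.na(pat), priors$lambda0, pat)
    h <- alpha_h / beta_h
    psi <- priors$beta0_eps / priors$alpha0_eps  # used for non-het rows
    theta <- 0
    m <- rep(1, n)
    Phi <- if (phi_free) priors$V0 / (priors$v0 - q2 - 1) else spec$phi_fixed
    if (phi_free && priors$v0 <= q2 + 1) Phi <- priors$V0  # improper mean
    Pi <- if (q1) ifelse(is.na(spec$Pi), priors$m0, spec$Pi) else spec$Pi
    Gamma <- if (q1) ifelse(is.na(spec$Gamma), priors$m0, spec$Gamma) else
      spec$Gamma
    Psi_delta <- if (q1) priors$beta0_delta / priors$alpha0_delta else
      numeric(0)
    W <- matrix(0, n, k)
    sweep_params <- list(spec = spec, Pi = Pi, Gamma = Gamma, Phi = Phi,
                         Psi_delta = Psi_delta)

    out <- matrix(NA_real_, nstore, length(cn),
                  dimnames = list(NULL, cn))
    lat_out <- if (config$store_latent) array(NA_real_, c(nstore, n, k))
    acc <- 0L; n_mh <- 0L; row <- 0L

    sigma_omega <- .sigma_omega_state(spec, Pi, Gamma, Phi, Psi_delta)

    for (s in seq_len(S)) {
      # (1) latent scores
      V <- matrix(rep(psi, each = n), n, p)
      if (use_law) V[, kh] <- (m / h) %o% rep(1, length(kh))
      W <- .draw_scores_raw(y, V, Lambda, sigma_omega)

      # (2) loading rows
      for (i in seq_len(p)) {
        fr <- free_rows[[i]]
        if (!length(fr)) next
        X <- W[, fr, drop = FALSE]
        fixed_cols <- setdiff(seq_len(k), fr)
        off <- if (length(fixed_cols))
          W[, fixed_cols, drop = FALSE] %*% pat[i, fixed_cols] else 0
        yk <- y[, i] - off
        if (het[i] && use_law) {
          Lambda[i, fr] <- draw_loading_row(yk, X, h, m,
                                            priors$lambda0[i, fr],
                                            priors$h0_lambda[i, fr])
        } else {
          Lambda[i, fr] <- draw_loading_row(yk, X, 1 / psi[i], rep(1, n),
                                            priors$lambda0[i, fr],
                                            priors$h0_lambda[i, fr])
        }
      }

      # (3) measurement precisions
      E <- y - W %*% t(Lambda)
      if (use_law) {
        h <- draw_precision(as.vector(E[, kh]),
                            rep(m, length(kh)), alpha_h, beta_h)
      }
      for (i in nh) {
        psi[i] <- 1 / draw_precision(E[, i], rep(1, n),
                                     priors$alpha0_eps[i],
                                     priors$beta0_eps[i])
      }

      # (4) structural rows + residual precisions
      if (q1 > 0) {
        for (l in seq_len(q1)) {
          fp <- which(is.na(spec$Pi[l, ]))
          fg <- which(is.na(spec$Gamma[l, ]))
          Xs <- cbind(W[, fp, drop = FALSE],
                      W[, q1 + fg, drop = FALSE])
          fix_p <- setdiff(seq_len(q1), fp)
          fix_g <- setdiff(seq_len(q2), fg)
          off <- rep(0, n)
          if (length(fix_p)) off <- off +
              W[, fix_p, drop = FALSE] %*% spec$Pi[l, fix_p]
          if (length(fix_g)) off <- off +
              W[, q1 + fix_g, drop = FALSE] %*% spec$Gamma[l, fix_g]
          resp <- W[, l] - off
          if (ncol(Xs)) {
            cf <- draw_loading_row(resp, Xs, 1 / Psi_delta[l], rep(1, n),
                                   rep(priors$m0, ncol(Xs)),
                                   rep(priors$h0_m, ncol(Xs)))
            if (length(fp)) Pi[l, fp] <- cf[seq_along(fp)]
            if (length(fg)) Gamma[l, fg] <- cf[length(fp) + seq_along(fg)]
          }
          ed <- resp - if (ncol(Xs)) Xs %*% c(if (length(fp)) Pi[l, fp],
                                              if (length(fg)) Gamma[l, fg])
                       else 0
          Psi_delta[l] <- 1 / draw_precision(as.vector(ed), rep(1, n),
                                             priors$alpha0_delta[l],
                                             priors$beta0_delta[l])
        }
      }

      # (5) factor covariance
      if (phi_free) {
        Phi <- draw_factor_cov(W[, q1 + seq_len(q2), drop = FALSE],
                               priors$v0, priors$V0)
      }
      if (q1 > 0 || phi_free) {
        sigma_omega <- .sigma_omega_state(spec, Pi, Gamma, Phi, Psi_delta)
      }

      # (6) variance-law coefficient (Metropolis)
      if (use_law) {
        mh <- draw_varlaw_coeffs(E[, kh, drop = FALSE], z, form, theta,
                                 h, priors$varlaw_mean, priors$varlaw_sd,
                                 config$proposal_scale, normalize = TRUE)
        n_mh <- n_mh + 1L
        if (mh$accepted) {
          acc <- acc + 1L
          if (mh$coeffs != theta) {
            theta <- mh$coeffs
            m <- variance_profile(mh$law, z)
          }
        }
        if (!is.finite(h) || !is.finite(theta)) {
          stop("divergent state at iteration ", s, ", block varlaw/precision",
               ", chain ", ch)
        }
      }

      # (7) record
      if (s > S0 && (s - S0) %% thin == 0L) {
        row <- row + 1L
        vals <- unlist(lapply(seq_len(p), function(i)
          Lambda[i, free_rows[[i]]]))
        if (use_law) vals <- c(vals, h, theta)
        if (length(nh)) vals <- c(vals, psi[nh])
        ev <- ifelse(het, mean(m) / h, psi)
        vals <- c(vals, ev)
        if (q1 > 0) {
          for (l in seq_len(q1)) {
            fp <- which(is.na(spec$Pi[l, ]))
            fg <- which(is.na(spec$Gamma[l, ]))
            vals <- c(vals, if (length(fp)) Pi[l, fp],
                      if (length(fg)) Gamma[l, fg], Psi_delta[l])
          }
        }
        if (phi_free) vals <- c(vals, Phi[upper.tri(Phi, diag = TRUE)])
        if (any(!is.finite(vals))) {
          stop("divergent state at iteration ", s, ", chain ", ch)
        }
        out[row, ] <- vals
        if (config$store_latent) lat_out[row, , ] <- W
      }
    }
    chains[[ch]] <- out
    if (config$store_latent) latent[[ch]] <- lat_out
    acc_rates[ch] <- if (n_mh) acc / n_mh else NA_real_
  }

  structure(list(draws = chains, param_names = cn, spec = spec,
                 priors = priors, form = form, config = config,
                 acceptance = acc_rates, chain_seeds = chain_seeds,
                 latent = if (config$store_latent) latent),
            class = "sem_chains")
}

.sigma_omega_state <- function(spec, Pi, Gamma, Phi, Psi_delta) {
  if (spec$q1 == 0L) return((Phi + t(Phi)) / 2)
  Pi0 <- diag(spec$q1) - Pi
  Pi0_inv <- solve(Pi0)
  GPhi <- Gamma %*% Phi
  tl <- Pi0_inv %*% (GPhi %*% t(Gamma) + diag(Psi_delta, spec$q1)) %*%
    t(Pi0_inv)
  tr <- Pi0_inv %*% GPhi
  out <- rbind(cbind(tl, tr), cbind(t(tr), Phi))
  (out + t(out)) / 2
}

#' @export
print.sem_chains <- function(x, ...) {
  nd <- sum(vapply(x$draws, nrow, 1L))
  cat("<sem_chains>", length(x$draws), "chain(s),", nd,
      "retained draws,", length(x$param_names), "parameters\n")
  cat("  form:", x$form, " MH acceptance:",
      paste(signif(x$acceptance, 3), collapse = ", "), "\n")
  invisible(x)
}
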