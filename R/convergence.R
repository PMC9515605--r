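#' Convergence diagnostics for stored chains
#'
#' Computes the split-chain potential-scale-reduction statistic (each chain
#' is halved, so even a single chain yields two sub-chains) and an
#' effective sample size from the initial-positive-sequence autocorrelation
#' sum, per scalar parameter.  Parameters with scale reduction above 1.05
#' are flagged; zero-variance (constant) parameters are flagged
#' `"degenerate"` rather than returning NaN.
#'
#' @param chains A `sem_chains` object, or a list of draw matrices with
#'   identical column names.
#' @return Data frame with columns `parameter`, `rhat`, `ess`, `flag`.
#' @export
convergence_report <- function(chains) {
  draws <- if (inherits(chains, "sem_chains")) chains$draws else chains
  stopifnot(is.list(draws), length(draws) >= 1L)
  nret <- nrow(draws[[1L]])
  if (length(draws) < 2L && nret < 200L) {
    stop("too few draws: need >= 2 chains or >= 200 retained draws")
  }
  pn <- colnames(draws[[1L]])
  res <- lapply(seq_along(pn), function(j) {
    xs <- lapply(draws, function(d) d[, j])
    half <- unlist(lapply(xs, function(x) {
      h <- length(x) %/% 2L
      list(x[seq_len(h)], x[h + seq_len(h)])
    }), recursive = FALSE)
    mns <- vapply(half, mean, 1)
    vrs <- vapply(half, stats::var, 1)
    W <- mean(vrs)
    nn <- length(half[[1L]])
    B <- nn * stats::var(mns)
    if (!is.finite(W) || W <= 0) {
      if (stats::var(mns) > 1e-12) {
        # disjoint constant chains: between-variance without within-variance
        return(data.frame(parameter = pn[j], rhat = Inf, ess = NA_real_,
                          flag = "divergent"))
      }
      return(data.frame(parameter = pn[j], rhat = NA_real_, ess = NA_real_,
                        flag = "degenerate"))
    }
    rhat <- sqrt(((nn - 1) / nn * W + B / nn) / W)
    ess <- sum(vapply(xs, .ess_one, 1))
    data.frame(parameter = pn[j], rhat = rhat, ess = ess,
               flag = if (rhat > 1.05) "high-rhat" else "ok")
  })
  do.call(rbind, res)
}

# effective sample size of one chain (Geyer initial positive sequence)
.ess_one <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0) return(NA_real_)
  max_lag <- min(n - 1L, 1000L)
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1L]
  s <- 0
  for (l in seq(1L, length(rho) - 1L, by = 2L)) {
    pair <- rho[l] + rho[l + 1L]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}
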