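#' Read / write datasets as CSV
#'
#' The on-disk format is a header CSV with indicator columns `y1..yp` and a
#' driver column `z`; no index column.
#'
#' @param path File path.
#' @return [read_sem_dataset()] returns a `sem_dataset`.
#' @export
read_sem_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  ycols <- grep("^y[0-9]+$", names(df), value = TRUE)
  if (!length(ycols)) stop("no indicator columns y1..yp found in ", path)
  ycols <- ycols[order(as.integer(sub("^y", "", ycols)))]
  if (!"z" %in% names(df)) stop("no driver column 'z' found in ", path)
  sem_dataset(as.matrix(df[ycols]), df$z)
}

#' @rdname read_sem_dataset
#' @param data A `sem_dataset`.
#' @export
write_sem_dataset <- function(data, path) {
  stopifnot(inherits(data, "sem_dataset"))
  df <- data.frame(data$y, z = data$z, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load a model / prior / sampler configuration from JSON
#'
#' Recognised top-level keys: `model` (`p`, `heteroscedastic`,
#' `phi_fixed`), `variance_law` (`form`, `coeffs`), `priors` (`preset`
#' plus any [prior_spec()] override), `sampler` (any [sampler_config()]
#' argument).  Unknown keys raise an error naming the offender.
#'
#' @param path JSON file path.
#' @return List with `spec`, `priors`, `form`, `config`.
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("model", "variance_law", "priors", "sampler")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  mod <- cfg$model
  if (!is.null(mod)) {
    mbad <- setdiff(names(mod), c("p", "heteroscedastic", "phi_fixed"))
    if (length(mbad)) stop("unknown model key(s): ",
                           paste(mbad, collapse = ", "))
  }
  p <- if (!is.null(mod$p)) as.integer(mod$p) else 2L
  spec <- sem_spec(matrix(NA_real_, p, 1), n_exogenous = 1L,
                   phi_fixed = matrix(
                     if (!is.null(mod$phi_fixed)) mod$phi_fixed else 1,
                     1, 1),
                   heteroscedastic =
                     if (!is.null(mod$heteroscedastic))
                       as.logical(mod$heteroscedastic) else rep(TRUE, p))
  form <- if (!is.null(cfg$variance_law$form)) cfg$variance_law$form else
    "linear"
  if (!form %in% c("double_log", "linear", "linear_inverse",
                   "linear_absolute")) {
    stop("unknown variance_law form: ", form)
  }
  preset <- if (!is.null(cfg$priors$preset)) cfg$priors$preset else
    "informative"
  priors <- prior_preset(spec, preset)
  samp <- cfg$sampler
  if (!is.null(samp)) {
    sbad <- setdiff(names(samp),
                    c("n_iterations", "burn_in", "n_chains", "seed",
                      "thin", "store_latent", "proposal_scale"))
    if (length(sbad)) stop("unknown sampler key(s): ",
                           paste(sbad, collapse = ", "))
    config <- do.call(sampler_config, samp)
  } else {
    config <- sampler_config()
  }
  list(spec = spec, priors = priors, form = form, config = config)
}
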