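# Proteomics preprocessing: low-coverage filtering followed by
# downshifted-Gaussian (Perseus-style, total-matrix) imputation of
# left-censored missing values.

#' Imputation configuration
#'
#' @param width Width of the imputation distribution as a fraction of the
#'   pooled observed standard deviation (default 0.3).
#' @param downshift Downward shift of the imputation mean in pooled observed
#'   standard deviations (default 1.8).
#' @param min_observed_frac Features observed in at most this fraction of
#'   samples are removed (strict `>` retention, so exactly 10% observed is
#'   removed at the default 0.10).
#' @param seed Integer seed for the imputation draws.
#' @return An `imputation_config` list.
#' @export
imputation_config <- function(width = 0.3, downshift = 1.8,
                              min_observed_frac = 0.10, seed = 1) {
  stopifnot(width > 0, downshift > 0,
            min_observed_frac >= 0, min_observed_frac < 1)
  structure(list(width = width, downshift = downshift,
                 min_observed_frac = min_observed_frac, seed = as.integer(seed)),
            class = "imputation_config")
}

#' Remove low-coverage proteins
#'
#' A feature is retained iff its observed (non-missing) fraction strictly
#' exceeds `min_observed_frac`; the removed features are reported in a
#' message and in the `removed` attribute.
#'
#' @param mat Numeric matrix, features x samples, `NA` = missing.
#' @param config An [imputation_config()].
#' @return The filtered matrix (datatype attribute preserved).
#' @export
filter_low_coverage <- function(mat, config = imputation_config()) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L)
  observed_frac <- rowMeans(!is.na(mat))
  keep <- observed_frac > config$min_observed_frac
  if (!any(keep)) {
    stop("all features fall at or below the coverage threshold; review min_observed_frac",
         call. = FALSE)
  }
  removed <- rownames(mat)[!keep]
  if (length(removed)) {
    message(sprintf("filter_low_coverage: removed %d feature(s) observed in <= %.0f%% of samples",
                    length(removed), 100 * config$min_observed_frac))
  }
  out <- mat[keep, , drop = FALSE]
  attr(out, "datatype") <- attr(mat, "datatype")
  attr(out, "removed") <- removed
  out
}

#' Impute missing values from a downshifted Gaussian
#'
#' Pools ALL observed entries of the matrix (not per feature or per sample)
#' to estimate a mean `mu` and standard deviation `sigma`, then replaces
#' each missing entry with an independent draw from
#' `Normal(mu - downshift * sigma, (width * sigma)^2)`. Observed entries are
#' returned bit-identical; draws are deterministic under `config$seed` and
#' are not truncated.
#'
#' @param mat Numeric matrix with `NA` for missing entries.
#' @param config An [imputation_config()].
#' @return The matrix with all `NA` cells imputed; attribute
#'   `imputed_cells` holds the linear indices that were filled.
#' @export
impute_downshifted <- function(mat, config = imputation_config()) {
  stopifnot(is.matrix(mat))
  obs <- mat[!is.na(mat)]
  if (length(obs) < 2L) stop("need at least 2 observed values to fit the imputation distribution", call. = FALSE)
  mu <- mean(obs)
  sigma <- stats::sd(obs)
  if (sigma == 0) stop("observed values are degenerate (sd = 0); cannot impute", call. = FALSE)
  na_idx <- which(is.na(mat))
  if (!length(na_idx)) return(mat)
  set.seed(config$seed)
  draws <- stats::rnorm(length(na_idx),
                        mean = mu - config$downshift * sigma,
                        sd = config$width * sigma)
  out <- mat
  out[na_idx] <- draws
  attr(out, "datatype") <- attr(mat, "datatype")
  attr(out, "imputed_cells") <- na_idx
  out
}
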