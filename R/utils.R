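# Internal helpers shared across modules.

# Deterministic sub-seed derivation so each stochastic component of a run
# draws from its own substream: perturbing one component never shifts the
# draws of another. Result always fits in a 32-bit integer.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) + offset * 1000003) %% 2147483647)
}

# Missing-value spellings accepted in tab-separated inputs; nothing else.
MISSING_SPELLINGS <- c("", "NA", "NaN", "nan")

# Convert a character matrix cell-wise to numeric, reporting the first
# offending cell by row/column label instead of coercing silently.
parse_numeric_cells <- function(chr, row_labels, col_labels, allow_missing = TRUE) {
  chr <- as.matrix(chr)
  is_missing <- matrix(chr %in% MISSING_SPELLINGS, nrow = nrow(chr))
  num <- suppressWarnings(array(as.numeric(chr), dim = dim(chr)))
  bad <- !is_missing & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                 chr[idx[1L], idx[2L]], row_labels[idx[1L]], col_labels[idx[2L]]),
         call. = FALSE)
  }
  if (!allow_missing && any(is_missing)) {
    idx <- which(is_missing, arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at feature '%s', sample '%s' where none is allowed",
                 row_labels[idx[1L]], col_labels[idx[2L]]), call. = FALSE)
  }
  num[is_missing] <- NA_real_
  dimnames(num) <- list(row_labels, col_labels)
  num
}

# Full-precision numeric formatting so write-then-read is the identity.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1L))
  out
}

# FNV-1a hash of a serialized object; used for reproducible stage digests.
object_digest <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
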