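# Pathway activity scoring: a weighted sum of (optionally gene-standardized)
# expression against a gene-by-pathway coefficient matrix, with optional
# per-pathway standardization so scores are z-scores across patients.

#' Compute per-patient pathway activity scores
#'
#' Genes are intersected between the expression matrix and the coefficient
#' matrix (dropped genes are counted per pathway). With
#' `standardize_genes = TRUE` each gene row is centred and scaled to unit
#' variance across patients (n - 1 denominator); zero-variance genes are
#' excluded from scoring with a message. The raw score is
#' `s[i, p] = sum_g z[g, i] * W[g, p]`; with `standardize_scores = TRUE`
#' each pathway column is then centred/scaled across patients, yielding
#' z-score activities. Pathways with no shared responsive gene, or whose
#' raw score carries no variance (e.g. all-zero weights), are excluded with
#' a warning.
#'
#' @param expr Numeric matrix, genes x samples, no missing values.
#' @param weights Numeric matrix, genes x pathways.
#' @param standardize_genes,standardize_scores Flags, both on by default.
#' @return An `activity_scores` list: `scores` (samples x pathways),
#'   `genes_used` (named integer: responsive genes found per pathway),
#'   `dropped_pathways`.
#' @export
compute_activity_scores <- function(expr, weights, standardize_genes = TRUE,
                                    standardize_scores = TRUE) {
  stopifnot(is.matrix(expr), is.matrix(weights))
  if (anyNA(expr)) stop("expression matrix contains missing values; impute first", call. = FALSE)
  shared <- intersect(rownames(expr), rownames(weights))
  if (!length(shared)) stop("no genes shared between expression and coefficient matrix", call. = FALSE)

  X <- expr[shared, , drop = FALSE]
  W <- weights[shared, , drop = FALSE]

  if (standardize_genes) {
    sds <- apply(X, 1L, stats::sd)
    flat <- sds == 0 | is.na(sds)
    if (any(flat)) {
      message(sprintf("compute_activity_scores: %d zero-variance gene(s) excluded", sum(flat)))
      X <- X[!flat, , drop = FALSE]
      W <- W[!flat, , drop = FALSE]
      sds <- sds[!flat]
    }
    X <- (X - rowMeans(X)) / sds
  }

  genes_used <- colSums(W != 0)
  no_gene <- genes_used == 0L
  if (any(no_gene)) {
    warning("pathway(s) with no shared responsive gene excluded: ",
            paste(colnames(W)[no_gene], collapse = ", "), call. = FALSE)
  }
  S <- t(X) %*% W            # samples x pathways, raw weighted sums
  col_sd <- apply(S, 2L, stats::sd)
  flat_score <- col_sd == 0 | is.na(col_sd)
  drop <- no_gene | (standardize_scores & flat_score)
  if (any(flat_score & !no_gene) && standardize_scores) {
    warning("pathway(s) with constant raw scores excluded: ",
            paste(colnames(S)[flat_score & !no_gene], collapse = ", "), call. = FALSE)
  }
  S <- S[, !drop, drop = FALSE]
  if (!ncol(S)) stop("no scorable pathway remains", call. = FALSE)
  if (standardize_scores) {
    S <- scale(S)
    attr(S, "scaled:center") <- NULL
    attr(S, "scaled:scale") <- NULL
  }
  structure(list(scores = S,
                 genes_used = genes_used[!drop],
                 dropped_pathways = colnames(weights)[drop]),
            class = "activity_scores")
}

#' Associate pathway activity scores with event-free survival
#'
#' Each pathway's score vector is passed through the optimal cut-point scan
#' exactly as an expression feature would be, producing one screen row per
#' pathway with log2 HR, confidence interval, and minimum scan p-value.
#'
#' @param scores An `activity_scores` object (or a samples x pathways
#'   matrix).
#' @param survival Clinical data.frame.
#' @param thresholds A [significance_thresholds()]; default 0.05 / 0.5.
#' @return A `screen_table` with one row per pathway, sorted by p.
#' @export
score_survival_association <- function(scores, survival,
                                       thresholds = significance_thresholds()) {
  S <- if (inherits(scores, "activity_scores")) scores$scores else scores
  stopifnot(is.matrix(S))
  out <- screen_features(t(S), survival, thresholds = thresholds)
  out[order(out$p), , drop = FALSE]
}
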