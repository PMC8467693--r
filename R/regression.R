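# Cross-validated activity regression: LASSO feature selection at the
# one-standard-error lambda, Model-1/2/3-style feature assembly, and
# 10-fold cross-validated ordinary least squares with out-of-fold metrics.

#' LASSO feature selection with the one-standard-error rule
#'
#' Fits an L1-penalised least-squares path (internally standardized) over a
#' log-spaced lambda grid of length 100 spanning from `lambda_max` (the
#' smallest penalty with empty support) down by a factor of 1e-3, with
#' K-fold cross-validated mean squared error and its standard error per
#' lambda. `lambda_1se` is the largest lambda whose CV MSE lies within one
#' standard error of the minimum; the selected support is read there.
#'
#' @param X Numeric matrix, patients x features, no missing values.
#' @param y Numeric response (one pathway's activity score per patient).
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return A `lasso_path` list: `lambda`, `cv_mse`, `cv_mse_se`,
#'   `lambda_min`, `lambda_1se`, `support` (features nonzero at
#'   `lambda_1se`), `support_min`, `foldid`.
#' @export
lasso_select <- function(X, y, n_folds = 10, seed = 1) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y; impute first", call. = FALSE)
  n <- nrow(X)
  if (n_folds > n) stop("n_folds exceeds the number of patients", call. = FALSE)
  if (n < 2L * n_folds) stop("need at least 2 patients per fold", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)
  set.seed(derive_seed(seed, 11L))
  foldid <- sample(rep_len(seq_len(n_folds), n))
  cv <- glmnet::cv.glmnet(X, y, foldid = foldid, nlambda = 100,
                          lambda.min.ratio = 0.001, standardize = TRUE,
                          family = "gaussian")
  support_at <- function(s) {
    cf <- as.matrix(stats::coef(cv, s = s))
    rownames(cf)[-1L][cf[-1L, 1L] != 0]
  }
  structure(list(lambda = cv$lambda,
                 cv_mse = cv$cvm,
                 cv_mse_se = cv$cvsd,
                 lambda_min = cv$lambda.min,
                 lambda_1se = cv$lambda.1se,
                 support = support_at("lambda.1se"),
                 support_min = support_at("lambda.min"),
                 foldid = foldid),
            class = "lasso_path")
}

#' Assemble a model feature specification
#'
#' Either a fixed mechanistic feature list (Model-1 style), or the union of
#' a LASSO support and the top `k_top` prognostic features from a screen
#' (Model-2/3 style), de-duplicated preserving order (LASSO features first;
#' a feature in both is tagged `lasso_selected`).
#'
#' @param lasso_support Character vector of LASSO-selected features.
#' @param top_prognostic Character vector of prognostic features ordered by
#'   increasing p-value.
#' @param k_top How many top prognostic features to add (default 2).
#' @param fixed_list Optional fixed feature list; overrides selection.
#' @param name Model name.
#' @param source_tag `"mRNA"` or `"protein"`.
#' @return A `model_spec` list: `name`, `features`, `provenance`,
#'   `source_tag`.
#' @export
assemble_model_features <- function(lasso_support = character(0),
                                    top_prognostic = character(0),
                                    k_top = 2, fixed_list = NULL,
                                    name = "model", source_tag = "mRNA") {
  if (!is.null(fixed_list)) {
    features <- unique(fixed_list)
    provenance <- rep("mechanistic_list", length(features))
  } else {
    top <- utils::head(top_prognostic, k_top)
    features <- c(lasso_support, setdiff(top, lasso_support))
    provenance <- c(rep("lasso_selected", length(lasso_support)),
                    rep("top_prognostic", length(features) - length(lasso_support)))
  }
  if (!length(features)) stop("empty feature set for model '", name, "'", call. = FALSE)
  structure(list(name = name, features = features,
                 provenance = stats::setNames(provenance, features),
                 source_tag = source_tag),
            class = "model_spec")
}

#' Fit a cross-validated linear model for pathway activity
#'
#' Patients are partitioned into `n_folds` seeded folds of sizes differing
#' by at most one. For each fold an ordinary least-squares model is fitted
#' on the remaining folds and predicts the held-out patients, giving
#' out-of-fold predictions that cover every patient exactly once. Reported
#' metrics (RMSE, Pearson and Spearman correlation with two-sided p-values)
#' are computed on the out-of-fold predictions; reported coefficients and
#' standard errors come from a single full-data OLS fit. Collinear columns
#' are dropped with a warning before fitting.
#'
#' @param X Numeric matrix, patients x features (rownames = patient ids).
#' @param y Numeric response, aligned with `X` rows.
#' @param features Character vector of columns to use (default: all).
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @param foldid Optional externally supplied fold assignment (so several
#'   models can be compared on identical folds).
#' @param name Model name carried into reports.
#' @return A `model_fit` list with `coefficients` (term, estimate, se,
#'   t, p), `oof_predictions`, `rmse`, `rmse_insample`, `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p`, `n_folds`, `foldid`,
#'   `features`, `name`, `y`.
#' @export
fit_linear_cv <- function(X, y, features = colnames(X), n_folds = 10,
                          seed = 1, foldid = NULL, name = "model") {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  missing_feats <- setdiff(features, colnames(X))
  if (length(missing_feats)) {
    stop("feature(s) absent from X: ", paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  X <- X[, features, drop = FALSE]
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y; impute first", call. = FALSE)
  n <- nrow(X)
  if (n < n_folds) stop("fewer patients than folds", call. = FALSE)

  # drop collinear columns up front so every fold sees the same design
  qr_full <- qr(cbind(1, X))
  rank <- qr_full$rank
  if (rank < ncol(X) + 1L) {
    keep_idx <- sort(qr_full$pivot[seq_len(rank)])
    keep_idx <- keep_idx[keep_idx > 1L] - 1L
    warning(sprintf("rank-deficient design: dropped %d collinear feature(s)",
                    ncol(X) - length(keep_idx)), call. = FALSE)
    X <- X[, keep_idx, drop = FALSE]
  }

  if (is.null(foldid)) {
    set.seed(derive_seed(seed, 21L))
    foldid <- sample(rep_len(seq_len(n_folds), n))
  }
  stopifnot(length(foldid) == n)

  df <- as.data.frame(X)
  oof <- rep(NA_real_, n)
  for (k in sort(unique(foldid))) {
    test <- foldid == k
    fit_k <- stats::lm(y ~ ., data = cbind(y = y[!test], df[!test, , drop = FALSE]))
    oof[test] <- stats::predict(fit_k, newdata = df[test, , drop = FALSE])
  }
  stopifnot(!anyNA(oof))

  full <- stats::lm(y ~ ., data = cbind(y = y, df))
  cf <- summary(full)$coefficients
  coefficients <- data.frame(term = rownames(cf), estimate = cf[, 1L],
                             se = cf[, 2L], t = cf[, 3L], p = cf[, 4L],
                             row.names = NULL, stringsAsFactors = FALSE)

  rmse <- sqrt(mean((oof - y)^2))
  rmse_in <- sqrt(mean(stats::residuals(full)^2))
  pe <- stats::cor.test(oof, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(oof, y, method = "spearman", exact = FALSE))
  structure(list(name = name, features = colnames(X),
                 coefficients = coefficients,
                 oof_predictions = stats::setNames(oof, rownames(X)),
                 rmse = rmse, rmse_insample = rmse_in,
                 pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 n_folds = as.integer(n_folds), foldid = foldid,
                 seed = seed, y = y),
            class = "model_fit")
}

#' @exportS3Method base::print
print.model_fit <- function(x, ...) {
  cat(sprintf("Model '%s': %d features, %d-fold CV\n", x$name,
              length(x$features), x$n_folds))
  cat(sprintf("  out-of-fold RMSE = %.4f (in-sample %.4f)\n", x$rmse, x$rmse_insample))
  cat(sprintf("  Pearson R = %.4f (p = %.3g), Spearman rho = %.4f (p = %.3g)\n",
              x$pearson_r, x$pearson_p, x$spearman_rho, x$spearman_p))
  invisible(x)
}

#' Rank fitted models by out-of-fold error
#'
#' All fits must be on the same patients and the same response. Models are
#' sorted by out-of-fold RMSE ascending (ties broken by name) with their
#' correlation metrics side by side; the attribute `shared_features` lists
#' features used by more than one model.
#'
#' @param fits List of `model_fit` objects.
#' @return A data.frame, one row per model, sorted by RMSE.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1L), "model_fit")))
  y0 <- fits[[1L]]$y
  for (f in fits) {
    if (length(f$y) != length(y0) || any(f$y != y0)) {
      stop("models were fitted on different patients or responses", call. = FALSE)
    }
  }
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$name, n_features = length(f$features),
               rmse = f$rmse, rmse_insample = f$rmse_insample,
               pearson_r = f$pearson_r, spearman_rho = f$spearman_rho,
               corr_p = f$pearson_p, stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$rmse, tab$model), , drop = FALSE]
  rownames(tab) <- NULL
  all_feats <- unlist(lapply(fits, `[[`, "features"))
  attr(tab, "shared_features") <- sort(unique(all_feats[duplicated(all_feats)]))
  tab
}
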