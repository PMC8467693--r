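test_that("LASSO recovers an exact sparse signal and nothing much else", {
  set.seed(51)
  X <- matrix(rnorm(100 * 20), 100, 20, dimnames = list(NULL, paste0("x", 1:20)))
  y <- 2 * X[, 3] - X[, 7]
  path <- lasso_select(X, y, seed = 1)
  expect_true(all(c("x3", "x7") %in% path$support))
  expect_lte(length(path$support), 4L)
  # the one-SE rule picks a lambda at least as large as the CV minimum
  expect_gte(path$lambda_1se, path$lambda_min)
  expect_true(all(path$support %in% path$support_min))
  # CV error at lambda_1se within one SE of the minimum
  i1 <- which.min(abs(path$lambda - path$lambda_1se))
  imin <- which.min(path$cv_mse)
  expect_lte(path$cv_mse[i1], path$cv_mse[imin] + path$cv_mse_se[imin] + 1e-12)
})

test_that("LASSO input validation", {
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  expect_error(lasso_select(X, rep(1, 50)), "constant")
  expect_error(lasso_select(X, rnorm(50), n_folds = 60), "folds")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(lasso_select(Xna, rnorm(50)), "impute")
})

test_that("model assembly unions LASSO support with top prognostic features", {
  sp <- assemble_model_features(lasso_support = c("A", "B"),
                                top_prognostic = c("B", "C", "D"), k_top = 2)
  expect_identical(sp$features, c("A", "B", "C"))
  expect_identical(unname(sp$provenance["B"]), "lasso_selected")
  expect_identical(unname(sp$provenance["C"]), "top_prognostic")

  sp2 <- assemble_model_features(lasso_support = character(0),
                                 top_prognostic = c("A", "B"), k_top = 2)
  expect_identical(sp2$features, c("A", "B"))

  fixed <- c("APC", "AXIN1", "CTNNB1", "DKK2", "DVL2", "DVL3",
             "GSK3B", "LRP6", "SFRP1", "SFRP2", "WNT3")
  sp3 <- assemble_model_features(fixed_list = fixed, name = "mechanistic")
  expect_length(sp3$features, 11L)
  expect_true(all(sp3$provenance == "mechanistic_list"))

  expect_error(assemble_model_features(), "empty")
})

test_that("cross-validated OLS: noiseless recovery, out-of-fold coverage, rank handling", {
  set.seed(52)
  n <- 79
  X <- matrix(rnorm(n * 9), n, 9,
              dimnames = list(paste0("pt", 1:n), paste0("g", 1:9)))
  beta <- rnorm(9)
  y <- as.numeric(X %*% beta + 1.5)
  fit <- suppressWarnings(fit_linear_cv(X, y, seed = 3))
  expect_lt(fit$rmse, 1e-8)
  expect_gt(fit$pearson_r, 0.999999)
  # every patient predicted exactly once
  expect_length(fit$oof_predictions, n)
  expect_false(anyNA(fit$oof_predictions))
  # fold sizes differ by at most one
  expect_lte(diff(range(table(fit$foldid))), 1)

  # permuting patients (same folds by id) leaves rmse unchanged
  perm <- sample(n)
  fit_p <- suppressWarnings(fit_linear_cv(X[perm, ], y[perm],
                                          foldid = fit$foldid[perm], seed = 3))
  expect_equal(fit_p$rmse, fit$rmse, tolerance = 1e-10)

  # collinear design: dropped with a warning, fit still returned
  Xc <- cbind(X, g10 = X[, 1] * 2)
  expect_warning(fit_c <- fit_linear_cv(Xc, y + rnorm(n), seed = 3), "collinear")
  expect_lte(length(fit_c$features), 9L)
})

test_that("out-of-fold RMSE typically exceeds the in-sample RMSE", {
  set.seed(53)
  diffs <- replicate(20, {
    X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("g", 1:5)))
    y <- as.numeric(X %*% rnorm(5) + rnorm(60))
    f <- fit_linear_cv(X, y, seed = sample.int(1e6, 1))
    f$rmse - f$rmse_insample
  })
  expect_gt(median(diffs), 0)
})

test_that("model comparison ranks by out-of-fold error and requires shared patients", {
  set.seed(54)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("g", 1:6)))
  y <- as.numeric(X %*% c(2, -1, 0, 0, 0, 0) + rnorm(n, 0, 0.3))
  foldid <- sample(rep_len(1:10, n))
  good <- fit_linear_cv(X, y, features = c("g1", "g2"),
                        foldid = foldid, name = "signal")
  bad <- fit_linear_cv(X, y, features = c("g5", "g6"), foldid = foldid, name = "noise")
  tab <- compare_models(list(bad, good))
  expect_identical(tab$model, c("signal", "noise"))

  y2 <- y + 100
  other <- fit_linear_cv(X, y2, foldid = foldid, name = "other")
  expect_error(compare_models(list(good, other)), "different")

  # identical fits tie, stable order by name
  tie <- compare_models(list(fit_linear_cv(X, y, foldid = foldid, name = "b"),
                             fit_linear_cv(X, y, foldid = foldid, name = "a")))
  expect_identical(tie$model, c("a", "b"))
})
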