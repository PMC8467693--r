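test_that("identity weights reproduce gene z-scores", {
  set.seed(41)
  X <- matrix(rnorm(5 * 30), 5, 30,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
  W <- diag(5)
  dimnames(W) <- list(paste0("g", 1:5), paste0("g", 1:5))
  sc <- compute_activity_scores(X, W)
  z <- t(scale(t(X)))   # gene z-scores (n-1 convention)
  # each pathway column equals the corresponding gene z-score; the final
  # per-pathway standardization is the identity for unit-variance columns
  for (g in paste0("g", 1:5)) {
    expect_equal(unname(sc$scores[, g]), unname(z[g, ]), tolerance = 1e-10)
  }
  expect_equal(unname(sc$genes_used), rep(1L, 5), ignore_attr = TRUE)
})

test_that("standardized score columns have mean 0 and unit variance", {
  set.seed(42)
  X <- matrix(rnorm(40 * 25), 40, 25,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:25)))
  W <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(paste0("g", 1:40), paste0("PW", 1:3)))
  sc <- compute_activity_scores(X, W)
  expect_equal(unname(colMeans(sc$scores)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(sc$scores, 2, sd)), rep(1, 3), tolerance = 1e-10)
})

test_that("all-zero pathways are excluded and absent genes dropped, not zero-filled", {
  set.seed(43)
  X <- matrix(rnorm(10 * 20), 10, 20,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  W <- matrix(rnorm(12 * 2), 12, 2,
              dimnames = list(paste0("g", 1:12), c("PW1", "PW0")))
  W[, "PW0"] <- 0
  expect_warning(sc <- compute_activity_scores(X, W), "PW0")
  expect_identical(colnames(sc$scores), "PW1")
  # only the 10 shared genes count
  expect_lte(unname(sc$genes_used["PW1"]), 10L)
})

test_that("raw scoring is linear and permutation-equivariant", {
  set.seed(44)
  g <- paste0("g", 1:8); s <- paste0("s", 1:15)
  X1 <- matrix(rnorm(120), 8, 15, dimnames = list(g, s))
  X2 <- matrix(rnorm(120), 8, 15, dimnames = list(g, s))
  W <- matrix(rnorm(16), 8, 2, dimnames = list(g, c("A", "B")))
  raw <- function(X) compute_activity_scores(X, W, standardize_genes = FALSE,
                                             standardize_scores = FALSE)$scores
  expect_equal(raw(2 * X1 + X2), 2 * raw(X1) + raw(X2), tolerance = 1e-12)

  # permuting genes and patients permutes outputs correspondingly
  pg <- sample(g); ps <- sample(s)
  sc_perm <- compute_activity_scores(X1[pg, ps], W[pg, ], standardize_genes = FALSE,
                                     standardize_scores = FALSE)$scores
  expect_equal(sc_perm, raw(X1)[ps, ], tolerance = 1e-12)
})

test_that("noiseless cohorts recover the latent activities per pathway", {
  # cross-pathway leakage through shared responsive genes shrinks as the
  # panel grows; at 400 genes the per-pathway correlation exceeds 0.99
  cc <- cohort_config(n_patients = 150, n_genes = 400, n_pathways = 3,
                      noise_sd = 0, seed = 2)
  co <- generate_cohort(cc)
  sc <- suppressMessages(compute_activity_scores(co$expression, co$true_weights))
  for (p in colnames(sc$scores)) {
    expect_gte(abs(cor(sc$scores[, p], co$true_activities[, p])), 0.99)
  }
})

test_that("score-survival association screens pathways like features", {
  set.seed(46)
  n <- 80
  nc <- null_cohort_vectors(n)
  surv <- make_survival(nc$time, nc$event)
  S <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(surv$sample_id, c("PW1", "PW2")))
  tab <- score_survival_association(S, surv)
  expect_s3_class(tab, "screen_table")
  expect_setequal(tab$feature, c("PW1", "PW2"))
  expect_true(all(diff(tab$p) >= 0))   # sorted by p

  # constant score column -> degenerate flagged row
  S[, "PW2"] <- 1
  tab2 <- suppressWarnings(score_survival_association(S, surv))
  expect_true(!is.na(tab2$flag[tab2$feature == "PW2"]))
})
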