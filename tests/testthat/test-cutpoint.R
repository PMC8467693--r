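test_that("scan window arithmetic and degenerate features behave as specified", {
  set.seed(21)
  nc <- null_cohort_vectors(10)
  surv <- make_survival(nc$time, nc$event)

  # n = 10, min_frac 0.10: admissible low-group sizes are 1..9 for distinct values
  sc <- scan_cutpoints(stats::setNames(1:10 / 10, surv$sample_id), surv)
  expect_equal(sc$p_profile$fraction_low, (1:9) / 10)

  # constant feature: degenerate, p = 1
  scc <- scan_cutpoints(stats::setNames(rep(2, 10), surv$sample_id), surv)
  expect_true(scc$degenerate)
  expect_equal(scc$p_min, 1)
  expect_match(scc$reason, "constant")

  # fewer than 10 patients is a precondition failure
  expect_error(scan_cutpoints(stats::setNames(rnorm(6), paste0("s", 1:6)),
                              make_survival(1:6, rep(1, 6))), ">= 10")
})

test_that("minimum scanned p never exceeds the median-split p", {
  set.seed(22)
  for (i in 1:10) {
    n <- 40
    nc <- null_cohort_vectors(n)
    surv <- make_survival(nc$time, nc$event)
    v <- stats::setNames(rnorm(n), surv$sample_id)
    sc <- scan_cutpoints(v, surv)
    if (sc$degenerate) next
    med_row <- which.min(abs(sc$p_profile$fraction_low - 0.5))
    expect_lte(sc$p_min, sc$p_profile$p[med_row])
    expect_equal(sc$p_min, min(sc$p_profile$p))
    # chosen split respects the 10-90 window
    expect_gte(sc$frac_low, 0.10)
    expect_lte(sc$frac_low, 0.90)
  }
})

test_that("ties in p are broken toward the most balanced split, deterministically", {
  # perfectly symmetric null data force ties; rerun must pick the same split
  time <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  surv <- make_survival(time, rep(1, 10))
  v <- stats::setNames(seq(0.1, 1, 0.1), surv$sample_id)
  s1 <- scan_cutpoints(v, surv)
  s2 <- scan_cutpoints(v, surv)
  expect_identical(s1$best_cut_value, s2$best_cut_value)
  ties <- s1$p_profile$fraction_low[s1$p_profile$p == s1$p_min]
  expect_equal(abs(s1$frac_low - 0.5), min(abs(ties - 0.5)))
})

test_that("screen_features uses per-feature n, flags degenerates, and q = p for one test", {
  set.seed(23)
  n <- 60
  nc <- null_cohort_vectors(n)
  surv <- make_survival(nc$time, nc$event)
  X <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(c("gA", "gB", "gC"), surv$sample_id))
  X["gB", 1:20] <- NA            # per-feature missing patients
  X["gC", ] <- 5                 # constant
  scr <- suppressWarnings(screen_features(X, surv))
  expect_equal(scr$n[scr$feature == "gA"], n)
  expect_equal(scr$n[scr$feature == "gB"], n - 20L)
  expect_true(!is.na(scr$flag[scr$feature == "gC"]))
  expect_false(scr$significant[scr$feature == "gC"])

  # single-feature screen: q equals p (m = 1 bound with pi0 <= 1)
  scr1 <- screen_features(X["gA", , drop = FALSE], surv)
  expect_lte(scr1$q, scr1$p)

  # zero shared samples is an error
  colnames(X) <- paste0("other", seq_len(n))
  expect_error(screen_features(X, surv), "shared"
  )
})

test_that("significance calls use raw p and the fold-change threshold strictly", {
  thr_gene <- significance_thresholds(0.05, 0.5)
  thr_prot <- significance_thresholds(0.05, 1.0)
  expect_false(call_significant(list(p = 0.01, log2HR = 0.3), thr_gene))
  expect_true(call_significant(list(p = 0.04, log2HR = -1.2), thr_prot))
  expect_false(call_significant(list(p = 0.05, log2HR = 2), thr_gene))   # strict <
  expect_true(call_significant(list(p = 0.049, log2HR = 0.5), thr_gene)) # >= on |log2HR|
})

test_that("Storey q-values: bounds, order preservation, closed-form grid", {
  # single p: q = pi0 * p <= p
  expect_lte(storey_qvalues(0.03), 0.03)
  # all ones stay ones
  expect_equal(storey_qvalues(rep(1, 5)), rep(1, 5))
  # uniform grid p = 0.01..1.00: pi0 = 1 exactly and q_(i) = m p_(i) / i = 1
  expect_equal(storey_qvalues(seq(0.01, 1, by = 0.01)), rep(1, 100))
  # random vectors: in [0,1] and order-preserving
  set.seed(24)
  for (i in 1:5) {
    p <- runif(200)^1.5
    q <- storey_qvalues(p)
    expect_true(all(q >= 0 & q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(storey_qvalues(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("planted prognostic features are recovered with the right direction", {
  # strong planted effects: the screen's sign(log2HR) must match sign(beta)
  for (seed in 1:6) {
    cc <- cohort_config(n_patients = 600, n_genes = 30, n_pathways = 3,
                        noise_sd = 0.3,
                        prognostic_effects = c(g001 = 1, g002 = -1),
                        seed = seed)
    co <- generate_cohort(cc)
    for (f in c("g001", "g002")) {
      v <- stats::setNames(co$expression[f, ], co$survival$sample_id)
      sc <- scan_cutpoints(v, co$survival)
      expect_false(sc$degenerate)
      expected_sign <- if (f == "g001") 1 else -1
      expect_equal(sign(sc$logrank_at_best$log2_hr), expected_sign)
    }
  }
})
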