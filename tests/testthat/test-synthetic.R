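test_that("cohorts are bit-identical under the same seed, and substreams are independent", {
  cc <- cohort_config(n_patients = 60, n_genes = 20, n_pathways = 2, seed = 7)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(a$expression, b$expression)
  expect_identical(a$survival, b$survival)
  expect_identical(a$proteomics, b$proteomics)
  expect_identical(a$true_weights, b$true_weights)

  # planting survival effects must not change the expression substream
  cc_beta <- cohort_config(n_patients = 60, n_genes = 20, n_pathways = 2,
                           prognostic_effects = c(g001 = 1), seed = 7)
  c2 <- generate_cohort(cc_beta)
  expect_identical(c2$expression, a$expression)
  expect_identical(c2$true_weights, a$true_weights)
})

test_that("with no planted effects and no censoring, event times follow Exp(baseline)", {
  cc <- cohort_config(n_patients = 5000, n_genes = 3, n_pathways = 2,
                      baseline_hazard = 0.02, censoring_hazard = 0,
                      admin_censor_months = 1e7, seed = 4)
  co <- generate_cohort(cc)
  expect_equal(mean(co$survival$event), 1)
  # exponential mean 1/lambda = 50, sd 50 -> 3 SE band
  expect_lt(abs(mean(co$survival$time_months) - 50), 3 * 50 / sqrt(5000))
})

test_that("competing exponentials give event fraction lambda0/(lambda0+lambdac)", {
  cc <- cohort_config(n_patients = 5000, n_genes = 3, n_pathways = 2,
                      baseline_hazard = 0.02, censoring_hazard = 0.01,
                      admin_censor_months = 1e6, seed = 3)
  co <- generate_cohort(cc)
  p_exp <- 0.02 / 0.03
  expect_lt(abs(mean(co$survival$event) - p_exp),
            3 * sqrt(p_exp * (1 - p_exp) / 5000))
})

test_that("proteomics missingness is monotone decreasing in intensity", {
  cc <- cohort_config(n_patients = 400, n_genes = 50, seed = 11)
  co <- generate_cohort(cc)
  # reconstruct pre-mask intensities from the noiseless relation is not
  # possible; bin the parent expression of proteomics features instead
  prot_genes <- rownames(co$proteomics)
  parent <- co$expression[prot_genes, ]
  miss <- is.na(co$proteomics)
  bins <- cut(parent, breaks = stats::quantile(parent, seq(0, 1, 0.2)),
              include.lowest = TRUE)
  rate_by_bin <- tapply(as.vector(miss), bins, mean)
  expect_true(all(diff(rate_by_bin) < 0))
})

test_that("planted_truth reports prognostic directions and responsive genes", {
  cc <- cohort_config(n_patients = 30, n_genes = 10, n_pathways = 2,
                      prognostic_effects = c(g001 = 1, g002 = -0.5), seed = 2)
  tr <- planted_truth(generate_cohort(cc))
  expect_identical(tr$prognostic$direction,
                   c("increased_risk", "decreased_risk"))

  cc0 <- cohort_config(n_patients = 30, n_genes = 10, n_pathways = 2, seed = 2)
  expect_equal(nrow(planted_truth(generate_cohort(cc0))$prognostic), 0L)

  cc_full <- cohort_config(n_patients = 30, n_genes = 10, n_pathways = 2,
                           weight_density = 1, seed = 2)
  tr_full <- planted_truth(generate_cohort(cc_full))
  expect_true(all(vapply(tr_full$responsive, length, integer(1)) == 10L))

  expect_error(generate_cohort(
    cohort_config(n_patients = 30, n_genes = 10, prognostic_effects = c(nope = 1))),
    "nope")
})

test_that("write_cohort emits readable tables that match the in-memory cohort", {
  cc <- cohort_config(n_patients = 25, n_genes = 8, n_pathways = 2, seed = 9)
  co <- generate_cohort(cc)
  dir <- tempfile()
  write_cohort(co, dir)
  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(unname(expr), unname(co$expression), tolerance = 0)
  cl <- read_clinical_table(file.path(dir, "clinical.tsv"))
  expect_equal(cl$time_months, co$survival$time_months, tolerance = 0)
  prot <- read_expression_matrix(file.path(dir, "proteomics.tsv"), "protein")
  expect_identical(unname(is.na(prot)), unname(is.na(co$proteomics)))
})
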