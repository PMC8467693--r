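#' Configure a synthetic tumour cohort
#'
#' Defines the generative model used by [generate_cohort()]: latent
#' per-patient pathway activities drive gene expression through a sparse
#' gene-by-pathway weight matrix; event times are exponential with a hazard
#' log-linear in planted prognostic features; censoring is an independent
#' exponential truncated at an administrative horizon; and the proteomics
#' copy is masked missing-not-at-random, with low-intensity values more
#' likely missing.
#'
#' Defaults are sized after a mid-sized tumour cohort with roughly one
#' pathway-sized gene panel: 300 patients, 100 genes, 5 pathways, a baseline
#' hazard of 0.02 events/month (median event-free survival near 35 months),
#' light independent censoring and a 120-month administrative horizon.
#'
#' @param n_patients,n_genes,n_pathways Cohort dimensions (positive integers).
#' @param weight_density Fraction in (0, 1] of gene-pathway weights that are
#'   nonzero.
#' @param weight_scale Standard deviation of the nonzero weights.
#' @param noise_sd Standard deviation of the expression residual.
#' @param prognostic_effects Named numeric vector: log-hazard coefficient
#'   per planted prognostic feature (names must be generated gene ids,
#'   `g001`, `g002`, ...). Positive values are harmful.
#' @param baseline_hazard Baseline event hazard per month (> 0).
#' @param censoring_hazard Independent censoring hazard per month (>= 0).
#' @param admin_censor_months Administrative censoring horizon (> 0).
#' @param mnar_midpoint,mnar_steepness Logistic missingness parameters for
#'   the proteomics mask: P(missing | x) = 1 / (1 + exp(steepness * (x - midpoint))).
#' @param proteomics_frac Fraction of genes carried over into the proteomics
#'   table (a noisier, partially missing copy of their expression).
#' @param seed Integer seed; fixes every random draw via independent
#'   substreams (Mersenne-Twister).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 300, n_genes = 100, n_pathways = 5,
                          weight_density = 0.2, weight_scale = 1,
                          noise_sd = 0.5, prognostic_effects = numeric(0),
                          baseline_hazard = 0.02, censoring_hazard = 0.008,
                          admin_censor_months = 120,
                          mnar_midpoint = 0, mnar_steepness = 1.5,
                          proteomics_frac = 0.6, seed = 1) {
  stopifnot(n_patients >= 1, n_genes >= 1, n_pathways >= 1,
            weight_density > 0, weight_density <= 1,
            weight_scale > 0, noise_sd >= 0,
            baseline_hazard > 0, censoring_hazard >= 0,
            admin_censor_months > 0, mnar_steepness > 0,
            proteomics_frac > 0, proteomics_frac <= 1)
  if (length(prognostic_effects)) {
    stopifnot(is.numeric(prognostic_effects), !is.null(names(prognostic_effects)))
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_genes = as.integer(n_genes),
                 n_pathways = as.integer(n_pathways),
                 weight_density = weight_density,
                 weight_scale = weight_scale,
                 noise_sd = noise_sd,
                 prognostic_effects = prognostic_effects,
                 baseline_hazard = baseline_hazard,
                 censoring_hazard = censoring_hazard,
                 admin_censor_months = admin_censor_months,
                 mnar_midpoint = mnar_midpoint,
                 mnar_steepness = mnar_steepness,
                 proteomics_frac = proteomics_frac,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws latent standard-normal pathway activities per patient, maps them to
#' gene expression through a sparse weight matrix plus Gaussian residual,
#' simulates exponential event times with hazard
#' `baseline_hazard * exp(sum(beta_f * x_f))`, applies independent
#' exponential censoring truncated at the administrative horizon, and builds
#' a proteomics table as a noisier copy of a gene subset with logistic
#' intensity-dependent (MNAR) missingness.
#'
#' Each stochastic component (weights, activities, residual noise, survival,
#' proteomics noise, missingness) draws from its own seed substream, so the
#' same `seed` reproduces the cohort bit-identically and altering one
#' component does not perturb the others.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list with elements `expression` (genes x
#'   patients), `proteomics` (subset with `NA`s), `survival` (clinical
#'   data.frame), `true_weights` (genes x pathways), `true_activities`
#'   (patients x pathways) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  gene_ids <- sprintf("g%03d", seq_len(config$n_genes))
  sample_ids <- sprintf("P%04d", seq_len(config$n_patients))
  pathway_ids <- sprintf("PW%d", seq_len(config$n_pathways))

  unknown <- setdiff(names(config$prognostic_effects), gene_ids)
  if (length(unknown)) {
    stop("prognostic_effects name unknown feature(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  G <- config$n_genes; N <- config$n_patients; P <- config$n_pathways

  set.seed(derive_seed(config$seed, 1L))
  W <- matrix(0, G, P, dimnames = list(gene_ids, pathway_ids))
  nz <- matrix(stats::runif(G * P) < config$weight_density, G, P)
  W[nz] <- stats::rnorm(sum(nz), 0, config$weight_scale)

  set.seed(derive_seed(config$seed, 2L))
  A <- matrix(stats::rnorm(N * P), N, P, dimnames = list(sample_ids, pathway_ids))

  set.seed(derive_seed(config$seed, 3L))
  X <- W %*% t(A) + matrix(stats::rnorm(G * N, 0, config$noise_sd), G, N)
  dimnames(X) <- list(gene_ids, sample_ids)

  set.seed(derive_seed(config$seed, 4L))
  lp <- rep(0, N)
  for (f in names(config$prognostic_effects)) {
    lp <- lp + config$prognostic_effects[[f]] * X[f, ]
  }
  rate <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(N, rate = rate)
  c_time <- if (config$censoring_hazard > 0) {
    pmin(stats::rexp(N, rate = config$censoring_hazard), config$admin_censor_months)
  } else {
    rep(config$admin_censor_months, N)
  }
  time_obs <- pmin(t_event, c_time)
  event <- as.integer(t_event <= c_time)
  survival <- data.frame(sample_id = sample_ids, time_months = time_obs,
                         event = event, stringsAsFactors = FALSE)

  set.seed(derive_seed(config$seed, 5L))
  n_prot <- max(1L, as.integer(ceiling(config$proteomics_frac * G)))
  prot_genes <- sort(sample(gene_ids, n_prot))
  Prot <- X[prot_genes, , drop = FALSE] +
    matrix(stats::rnorm(n_prot * N, 0, config$noise_sd), n_prot, N)

  set.seed(derive_seed(config$seed, 6L))
  p_miss <- 1 / (1 + exp(config$mnar_steepness * (Prot - config$mnar_midpoint)))
  Prot[stats::runif(length(Prot)) < p_miss] <- NA_real_

  attr(X, "datatype") <- "mRNA"
  attr(Prot, "datatype") <- "protein"
  structure(list(expression = X, proteomics = Prot, survival = survival,
                 true_weights = W, true_activities = A, config = config),
            class = "synthetic_cohort")
}

#' Ground truth planted in a synthetic cohort
#'
#' Summarises what downstream recovery tests need: which features were given
#' nonzero log-hazard coefficients (and in which direction), and which genes
#' carry nonzero weight for each pathway.
#'
#' @param cohort A `synthetic_cohort`.
#' @return A list with `prognostic` (data.frame: feature, beta, direction)
#'   and `responsive` (named list: pathway -> genes with nonzero weight).
#' @export
planted_truth <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  beta <- cohort$config$prognostic_effects
  prognostic <- data.frame(feature = names(beta) %||% character(0),
                           beta = as.numeric(beta),
                           direction = ifelse(as.numeric(beta) > 0,
                                              "increased_risk", "decreased_risk"),
                           stringsAsFactors = FALSE)
  if (!length(beta)) prognostic <- prognostic[0, , drop = FALSE]
  W <- cohort$true_weights
  responsive <- lapply(colnames(W), function(p) rownames(W)[W[, p] != 0])
  names(responsive) <- colnames(W)
  list(prognostic = prognostic, responsive = responsive)
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d genes, %d pathways (seed %d)\n",
              x$config$n_patients, x$config$n_genes, x$config$n_pathways,
              x$config$seed))
  cat(sprintf("  events: %d/%d; proteomics: %d features, %.1f%% missing\n",
              sum(x$survival$event), nrow(x$survival), nrow(x$proteomics),
              100 * mean(is.na(x$proteomics))))
  invisible(x)
}

#' Write the four cohort tables plus ground truth to a directory
#'
#' Emits `expression.tsv`, `proteomics.tsv`, `clinical.tsv`,
#' `true_weights.tsv` and `truth.json` in the package's tab-separated
#' dialects, so a simulated cohort can stand in for downloaded data files.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  write_expression_matrix(cohort$proteomics, file.path(dir, "proteomics.tsv"))
  write_clinical_table(cohort$survival, file.path(dir, "clinical.tsv"))
  write_coefficient_matrix(cohort$true_weights, file.path(dir, "true_weights.tsv"))
  truth <- planted_truth(cohort)
  jsonlite::write_json(list(prognostic = truth$prognostic,
                            responsive = truth$responsive),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
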