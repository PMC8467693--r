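# End-to-end orchestration: simulate (or load) -> screen genes/proteins ->
# prep proteomics -> score pathways -> score-survival -> fit/compare models.

#' Run the full analysis pipeline
#'
#' Executes the stages of the analysis in order under one configuration and
#' seed, returning a machine-readable run report. The configuration is a
#' list (or a path to a YAML file) with exactly one of:
#'
#' * `simulate`: arguments for [cohort_config()]; the cohort (and its true
#'   weight matrix) is generated in memory, or
#' * `paths`: list with `expression`, `clinical`, `weights` and optionally
#'   `proteomics` file paths in the package's tab-separated dialects.
#'
#' Optional elements: `thresholds` (list with `mRNA`/`protein` lists of
#' `p_cutoff`, `log2fc_cutoff`), `imputation` (arguments for
#' [imputation_config()]), `scoring` (`standardize_genes`,
#' `standardize_scores`), `models` (named list; each entry either
#' `list(fixed_features = c(...), source = "mRNA")` or
#' `list(lasso = TRUE, k_top = 2, source = "mRNA", pathway = "PW1")`),
#' `pathway` (response pathway for the models; default: the pathway most
#' associated with survival), `folds` and `seed` (mandatory).
#'
#' @param config List or YAML file path.
#' @param out_dir Optional directory; when given, intermediate tables (TSV)
#'   and the JSON report are written there.
#' @return A `run_report` list; every executed stage appears exactly once
#'   with a reproducible content digest and parameter echo.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  has_sim <- !is.null(config$simulate)
  has_paths <- !is.null(config$paths)
  if (has_sim == has_paths) {
    stop("config must contain exactly one of 'simulate' or 'paths'", call. = FALSE)
  }
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  seed <- as.integer(config$seed)
  folds <- as.integer(config$folds %||% 10L)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  report <- list(software = paste("mechsurv", as.character(utils::packageVersion("mechsurv"))),
                 seed = seed, stages = list())
  add_stage <- function(name, params, output) {
    report$stages[[name]] <<- list(params = params, digest = object_digest(output))
  }
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
  }

  # -- stage: data --------------------------------------------------------
  if (has_sim) {
    cohort <- tryCatch({
      cc <- do.call(cohort_config, c(config$simulate, list(seed = seed)))
      generate_cohort(cc)
    }, error = function(e) fail("data", e))
    expr <- cohort$expression
    prot <- cohort$proteomics
    clinical <- cohort$survival
    weights <- cohort$true_weights
  } else {
    cohort <- NULL
    expr <- tryCatch(read_expression_matrix(config$paths$expression, "mRNA"),
                     error = function(e) fail("data", e))
    clinical <- tryCatch(read_clinical_table(config$paths$clinical),
                         error = function(e) fail("data", e))
    weights <- tryCatch(read_coefficient_matrix(config$paths$weights),
                        error = function(e) fail("data", e))
    prot <- if (!is.null(config$paths$proteomics)) {
      tryCatch(read_expression_matrix(config$paths$proteomics, "protein"),
               error = function(e) fail("data", e))
    }
  }
  add_stage("data", list(simulated = has_sim,
                         n_samples = ncol(expr), n_genes = nrow(expr)),
            list(expr, clinical, weights, prot))

  thr_gene <- do.call(significance_thresholds,
                      config$thresholds$mRNA %||% list(p_cutoff = 0.05, log2fc_cutoff = 0.5))
  thr_prot <- do.call(significance_thresholds,
                      config$thresholds$protein %||% list(p_cutoff = 0.05, log2fc_cutoff = 1.0))

  # -- stage: gene screen -------------------------------------------------
  gene_screen <- tryCatch(
    suppressMessages(screen_features(expr, clinical, thresholds = thr_gene)),
    error = function(e) fail("screen_genes", e))
  add_stage("screen_genes",
            list(p_cutoff = thr_gene$p_cutoff, log2fc_cutoff = thr_gene$log2fc_cutoff),
            gene_screen)

  # -- stage: proteomics prep + screen ------------------------------------
  prot_screen <- NULL
  prot_imputed <- NULL
  if (!is.null(prot)) {
    imp_cfg <- do.call(imputation_config,
                       c(config$imputation %||% list(), list(seed = derive_seed(seed, 31L))))
    prot_imputed <- tryCatch(
      suppressMessages(impute_downshifted(filter_low_coverage(prot, imp_cfg), imp_cfg)),
      error = function(e) fail("prep_proteomics", e))
    add_stage("prep_proteomics",
              list(width = imp_cfg$width, downshift = imp_cfg$downshift,
                   min_observed_frac = imp_cfg$min_observed_frac),
              prot_imputed)
    prot_screen <- tryCatch(
      suppressMessages(screen_features(prot, clinical, thresholds = thr_prot)),
      error = function(e) fail("screen_proteins", e))
    add_stage("screen_proteins",
              list(p_cutoff = thr_prot$p_cutoff, log2fc_cutoff = thr_prot$log2fc_cutoff),
              prot_screen)
  }

  # -- stage: pathway scores + survival association -----------------------
  sc_flags <- config$scoring %||% list()
  scores <- tryCatch(
    suppressMessages(compute_activity_scores(
      expr, weights,
      standardize_genes = sc_flags$standardize_genes %||% TRUE,
      standardize_scores = sc_flags$standardize_scores %||% TRUE)),
    error = function(e) fail("score", e))
  add_stage("score", sc_flags, scores$scores)

  score_surv <- tryCatch(
    suppressMessages(score_survival_association(scores, clinical)),
    error = function(e) fail("score_survival", e))
  add_stage("score_survival", list(), score_surv)

  # -- stage: models ------------------------------------------------------
  model_table <- NULL
  fits <- list()
  if (!is.null(config$models)) {
    target_pathway <- config$pathway %||% score_surv$feature[1L]
    y <- scores$scores[, target_pathway]
    set.seed(derive_seed(seed, 41L))
    shared_foldid <- sample(rep_len(seq_len(folds), length(y)))
    for (mname in names(config$models)) {
      m <- config$models[[mname]]
      source <- m$source %||% "mRNA"
      Xsrc <- if (source == "protein") {
        if (is.null(prot_imputed)) fail(mname, simpleError("no proteomics data for a protein model"))
        prot_imputed
      } else expr
      Xm <- t(Xsrc[, names(y)[names(y) %in% colnames(Xsrc)], drop = FALSE])
      yk <- y[rownames(Xm)]
      spec <- tryCatch({
        if (!is.null(m$fixed_features)) {
          assemble_model_features(fixed_list = m$fixed_features, name = mname,
                                  source_tag = source)
        } else {
          las <- lasso_select(Xm, yk, n_folds = folds, seed = derive_seed(seed, 42L))
          screen_src <- if (source == "protein") prot_screen else gene_screen
          top <- screen_src$feature[order(screen_src$p)]
          top <- top[top %in% colnames(Xm)]
          assemble_model_features(lasso_support = las$support, top_prognostic = top,
                                  k_top = m$k_top %||% 2, name = mname,
                                  source_tag = source)
        }
      }, error = function(e) fail(mname, e))
      fit <- tryCatch(
        fit_linear_cv(Xm, yk, features = intersect(spec$features, colnames(Xm)),
                      n_folds = folds, foldid = shared_foldid[seq_along(yk)],
                      name = mname),
        error = function(e) fail(mname, e))
      fits[[mname]] <- fit
    }
    model_table <- compare_models(fits)
    add_stage("models", list(pathway = target_pathway, folds = folds), model_table)
  }

  report$screen_summary <- list(
    genes = list(n_features = nrow(gene_screen),
                 n_significant = sum(gene_screen$significant)),
    proteins = if (!is.null(prot_screen)) {
      list(n_features = nrow(prot_screen),
           n_significant = sum(prot_screen$significant))
    })
  report$score_survival <- score_surv
  report$model_comparison <- model_table
  report$fits <- fits
  report$cohort <- cohort
  report$gene_screen <- gene_screen
  report$protein_screen <- prot_screen
  report$scores <- scores

  if (!is.null(out_dir)) {
    utils::write.table(gene_screen, file.path(out_dir, "screen_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(prot_screen)) {
      utils::write.table(prot_screen, file.path(out_dir, "screen_proteins.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(as.data.frame(score_surv), file.path(out_dir, "score_survival.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(software = report$software, seed = report$seed,
           stages = report$stages, screen_summary = report$screen_summary,
           model_comparison = model_table),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  class(report) <- "run_report"
  report
}

#' Summarise a screen per gene set
#'
#' Counts, for each pathway gene set, the significant features (X), the
#' features with available data in the screen (Y), and the total set size
#' (Z) -- the X/Y/Z convention used when reporting per-pathway screen
#' results. A feature belonging to several sets is counted in each.
#'
#' @param screen A `screen_table`.
#' @param sets Named list of character vectors (see [read_gene_sets()]).
#' @return Data.frame: `pathway`, `n_significant`, `n_with_data`, `n_total`.
#' @export
summarize_screen <- function(screen, sets) {
  stopifnot(is.data.frame(screen), is.list(sets))
  rows <- lapply(names(sets), function(p) {
    members <- sets[[p]]
    in_screen <- screen$feature %in% members & is.na(screen$flag)
    data.frame(pathway = p,
               n_significant = sum(screen$significant & screen$feature %in% members),
               n_with_data = sum(in_screen),
               n_total = length(members),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
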