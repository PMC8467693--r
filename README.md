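# mechsurv

Mechanism-based survival screening and pathway activity modelling for
tumour cohorts.

Given feature-by-sample expression tables (mRNA or protein), a clinical
event-free-survival table, and a gene-by-pathway coefficient matrix,
mechsurv answers three questions that together link molecular features to
outcome:

1. **Which features are prognostic?** For each feature, patients are
   dichotomised at every admissible cut between the 10–90 and 90–10
   percent splits; each split is tested with a Yates-corrected log-rank
   test, and the minimum-p split is reported with a Pike (O/E) hazard
   ratio,

   HR = (O_high/E_high) / (O_low/E_low),  se(ln HR) = √(1/E_high + 1/E_low),

   in log2 with a Wald 95% CI. Storey positive-FDR q-values are computed
   across the screened set, and significance is called volcano-style:
   raw p < 0.05 and |log2 HR| ≥ 0.5 (genes) or ≥ 1.0 (proteins).
2. **How active is each pathway in each patient?** Activity is scored as
   a weighted sum of gene-standardized expression against the coefficient
   matrix, re-standardized per pathway into z-scores, and each pathway's
   score vector is passed through the same cut-point screen to measure
   its survival association.
3. **Which features explain the activity scores?** LASSO at the
   one-standard-error lambda selects a sparse panel, optionally unioned
   with the top prognostic features or replaced by a fixed mechanistic
   gene list; 10-fold cross-validated ordinary least squares then reports
   out-of-fold RMSE, Pearson R, Spearman rho, and full-data
   coefficients ± SE.

Proteomics inputs are preprocessed Perseus-style: proteins observed in
≤ 10% of samples are removed, and remaining missing values are drawn from
a downshifted Gaussian, N(μ − 1.8σ, (0.3σ)²), fitted on all observed
entries pooled across the matrix.

A seeded synthetic-cohort generator (`generate_cohort`) produces cohorts
with known ground truth — latent pathway activities driving expression
through a sparse coefficient matrix, exponential event times log-linear
in planted prognostic features, independent censoring, and
intensity-dependent (MNAR) proteomics missingness — so the entire chain
is testable offline. See the methods vignette
(`vignettes/mechsurv-methods.Rmd`) for the models, assumptions, and
numerical choices.

## Worked example

Simulate a cohort in which gene `g001` raises the hazard (β = 1), screen
all genes, and relate pathway scores to survival:

```r
library(mechsurv)

cc <- cohort_config(n_patients = 200, n_genes = 60, n_pathways = 3,
                    prognostic_effects = c(g001 = 1), seed = 42)
cohort <- generate_cohort(cc)
cohort
#> Synthetic cohort: 200 patients, 60 genes, 3 pathways (seed 42)
#>   events: 130/200; proteomics: 36 features, 50.5% missing

screen <- screen_features(cohort$expression, cohort$survival)
head(screen[order(screen$p), c("feature", "n", "frac_low", "log2HR",
                               "ci_low", "ci_high", "p", "significant")], 3)
#>    feature   n frac_low log2HR ci_low ci_high        p significant
#> 1     g001 200     0.69   2.30   1.57    3.03 4.81e-25        TRUE
#> 6     g006 200     0.30  -2.17  -2.89   -1.46 1.99e-21        TRUE
#> 10    g010 200     0.84   2.46   1.32    3.60 5.49e-20        TRUE
```

The planted gene tops the screen: its best split (69% low / 31% high)
separates survival with log2 HR = 2.30, i.e. roughly a 4.9-fold hazard in
the high-expression group, with CI well clear of zero. Genes such as
`g006` are prognostic too — they share latent pathway activity with the
planted gene — with the sign of their hazard ratio matching the sign of
their pathway weights. Under the minimum-p scan, p-values are
anti-conservative (see the vignette), so treat them as ranking scores.

```r
scores <- compute_activity_scores(cohort$expression, cohort$true_weights)
score_survival_association(scores, cohort$survival)[, c("feature", "n",
                           "frac_low", "log2HR", "p", "significant")]
#>   feature   n frac_low log2HR        p significant
#> 2     PW2 200    0.240 -2.383 2.08e-24        TRUE
#> 1     PW1 200    0.895  0.774 5.39e-02       FALSE
#> 3     PW3 200    0.200  0.657 8.06e-02       FALSE
```

Pathway PW2 — the pathway to which `g001` is most strongly responsive in
this cohort (with a negative weight, hence the negative log2 HR) — shows
the strongest survival association. A full log-rank report for any
feature is available directly:

```r
v <- setNames(cohort$expression["g001", ], cohort$survival$sample_id)
scan_cutpoints(v, cohort$survival)$logrank_at_best
#> Log-rank test (Yates-corrected p): chi2 = 109.6638, chi2_yates = 106.8477, p = 4.807e-25
#>   O (low/high) = 74/56, E = 112.690/17.310, V = 13.650
#>   log2 HR = 2.301 [1.571, 3.031], n = 138/62
```

`run_pipeline()` chains all stages (screen, proteomics prep, scoring,
score–survival, LASSO/OLS model comparison) under one config and seed
and writes tab-separated tables plus a JSON report.

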