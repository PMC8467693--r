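---
title: "Methods: survival screening, pathway scoring, and activity regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival screening, pathway scoring, and activity regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechsurv)
```

mechsurv connects three analyses that together relate tumour expression
data to clinical outcome: (1) a per-feature event-free-survival screen
based on optimal cut-point Kaplan–Meier scanning, (2) pathway activity
scoring from a gene-by-pathway coefficient matrix, and (3) cross-validated
linear models that predict patient-specific pathway activity from gene or
protein features. This vignette explains each model, its assumptions, the
parameters that matter, and the numerical choices the implementation makes.

## Survival screening by cut-point scanning

For one feature (a gene's mRNA level, a protein's abundance, or a pathway
activity score) and a cohort with event-free survival times, the screen
asks: does any dichotomisation of the patients into "low" and "high"
expression groups separate their survival curves?

The machinery is classical. The Kaplan–Meier product-limit estimate over
the distinct event times $t_i$ is

$$\hat S(t) = \prod_{t_i \le t} \left(1 - \frac{d_i}{n_i}\right),$$

with $d_i$ events among $n_i$ at risk; at tied times, events are processed
before censorings, so a patient censored at $t$ is still at risk at $t$.
Two groups are compared with the log-rank test: at each event time the
expected high-group events under the null are $E = d\,n_h/n$ with
hypergeometric variance, summed into $O$, $E$, $V$, and
$\chi^2 = (O-E)^2/V$. The screen always applies Yates' continuity
correction, $\chi^2_Y = (\max(|O-E|-0.5,\,0))^2/V$, which is conservative
($\chi^2_Y \le \chi^2$ on every instance) and matters at the small group
sizes the scan window permits. The hazard ratio is the Pike O/E estimator

$$\widehat{HR} = \frac{O_h/E_h}{O_l/E_l}, \qquad
  se(\ln \widehat{HR}) = \sqrt{1/E_h + 1/E_l},$$

reported in log2 with a Wald 95% interval. No proportional-hazards
regression is fitted anywhere: the hazard ratio is derived from the same
O/E quantities as the test itself, which is the natural estimator to pair
with Kaplan–Meier-based reporting. The standard error is kept on the
natural-log scale internally; log2 quantities are the natural-log values
divided by $\ln 2$.

The scan sorts patients by feature value and tests **every** split between
distinct adjacent values whose low-group fraction lies in $[0.10, 0.90]$
(any coarser percent grid is a subset of this, so the finest grid is the
canonical choice). The reported p is the minimum over the profile. Ties in
p are broken toward the most balanced split, then toward the lower cut, so
the result is deterministic. Each feature is screened on the patients for
whom it is non-missing — per-feature n, not listwise deletion.

Two properties of this procedure deserve emphasis:

* **The minimum-p scan is anti-conservative.** Under the null the p-value
  at a *fixed* split is uniform, but the minimum over ~0.8·n splits is
  not: its null rejection rate at $\alpha = 0.05$ is several-fold inflated
  (the acceptance suite measures roughly 0.25–0.35 at n = 60). The package
  reports the scanned minimum p faithfully and leaves it uncorrected,
  because that is the procedure it implements; scan-adjusted p-values
  (e.g. Lausen–Schumacher) are a known improvement deliberately left out
  of scope. Interpret screen p-values as ranking scores, with the q-values
  as the multiplicity anchor across features.
* **Significance calls use raw p.** A feature is called significant when
  `p < p_cutoff` (strict) **and** `|log2 HR| >= log2fc_cutoff` — the
  volcano-plot convention, with 0.5 as the conventional fold-change
  threshold for genes and 1.0 for proteins. q-values are reported
  alongside, not gated on.

### Storey q-values

Across the screened set the package computes positive-FDR q-values:
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ on the grid
$\lambda = 0.05, 0.10, \ldots, 0.90$, smoothed by a cubic polynomial
evaluated at $\lambda = 0.90$ and clamped into $(0, 1]$; then
$q_{(i)} = \hat\pi_0\, m\, p_{(i)}/i$ with the step-up monotonicity pass.
The cubic-at-max-lambda smoother is used rather than the spline variant
because it is fully determined by the grid values (no smoothing parameter)
and reproduces the reference procedure to numerical precision on dense
p-grids; on the uniform grid $p = 0.01, \ldots, 1.00$ the whole
construction collapses to $q \equiv 1$ exactly, which the tests freeze as
a closed-form check.

## Proteomics preprocessing

Mass-spectrometry proteomics is missing-not-at-random: low-abundance
measurements drop out. The package follows the Perseus convention:

1. **Coverage filter** — features observed in at most `min_observed_frac`
   (default 10%) of samples are removed; retention is strict (`>`), so a
   protein observed in exactly 10% of samples is dropped.
2. **Downshifted-Gaussian imputation** — the mean $\mu$ and standard
   deviation $\sigma$ of *all* observed entries pooled across the matrix
   are estimated, and every missing cell is drawn independently from
   $N(\mu - 1.8\sigma,\ (0.3\sigma)^2)$. Pooling is total-matrix by
   design; a per-sample mode is out of scope. Draws are not truncated.
   Observed cells are returned bit-identical and all draws are fixed by
   the imputation seed.

The default `width = 0.3` and `downshift = 1.8` are the standard
left-censored imputation parameters for label-based proteomics. Filtering
runs before imputation: imputing first would let features that are mostly
missing consist mostly of synthetic draws before being judged for
coverage. (The narrative order of the two steps is genuinely ambiguous in
common practice; both orders are trivially composable from the two
exported functions, filter-first is the default.)

## Pathway activity scoring

Pathway activity is inferred as a weighted sum of responsive-gene
expression against a gene-by-pathway coefficient matrix $W$ (the
"z-coefficients"): after centring and scaling each gene across patients,

$$s_{ip} = \sum_g z_{gi}\, W_{gp},$$

followed by per-pathway standardization so each activity column is a
z-score across the cohort (mean 0, variance 1; this is what produces the
familiar −3..3 score range). The coefficient matrix is an *input*:
estimating it from perturbation experiments is explicitly out of scope,
and a published responsive-gene coefficient matrix can be supplied
directly. Genes in $W$ that are absent from the expression matrix are
dropped and counted per pathway — zero-filling them would shrink scores
toward 0 for pathways with poor coverage, silently. Zero-variance genes
are excluded from standardization (centred, they contribute nothing
anyway). All variances use the unbiased $n-1$ denominator.

With gene standardization off, raw scoring is exactly linear in the
expression matrix, and reordering genes or patients permutes the output
correspondingly — both are enforced as properties in the tests.

The synthetic generator makes the fidelity of this scheme quantifiable:
when expression is generated as $x_g = \sum_p W_{gp} a_p + \varepsilon$
with known activities $a$, the computed scores correlate with the true
activities per pathway. The correlation is not exactly 1 even at zero
noise, because genes responsive to several pathways leak activity across
score columns; the leakage shrinks as the panel grows (cross terms grow
like $\sqrt{G}$ against the diagonal's $G$). At 400 genes and the default
20% weight density the per-pathway correlation exceeds 0.99, which is the
scale the fidelity tests use.

## Survival association of scores

Each pathway's score vector is passed through the *same* cut-point scan as
any expression feature, producing a log2 hazard ratio, confidence
interval, and minimum scan p per pathway. This deliberately reuses the
screening machinery unchanged, so the score-survival table is comparable
with the feature-level screen.

## Activity regression

The final stage asks how well a small feature panel predicts a pathway's
activity score.

* **LASSO selection** (`lasso_select`) runs L1-penalised least squares
  over a 100-point log-spaced lambda grid (down to $10^{-3}\lambda_{max}$)
  with 10-fold cross-validation, and reads the support at the
  one-standard-error lambda: the largest penalty whose CV MSE is within
  one SE of the minimum. This is the standard parsimony-biased rule; its
  support is nested in the lambda-min support in every test run. The path
  and CV machinery are delegated to glmnet; the surrounding contract
  (grid, 1-SE rule, support extraction, seeded folds) is this package's.
* **Feature assembly** (`assemble_model_features`) builds the three model
  archetypes: a fixed mechanistic gene list; or the union of the LASSO
  support with the top-k (default 2) most significant features from the
  survival screen, de-duplicated with LASSO provenance taking precedence.
  `k_top` is a parameter because the two sources can overlap arbitrarily.
* **Cross-validated OLS** (`fit_linear_cv`) partitions patients into 10
  seeded folds (sizes differing by at most one), fits ordinary least
  squares on 9 folds, predicts the held-out fold, and reports RMSE,
  Pearson R and Spearman rho **on the out-of-fold predictions** — the
  honest generalisation estimate; in-sample RMSE is emitted alongside.
  Both correlation flavours are always reported because conventions
  differ between plot annotations ("R" as Pearson) and text summaries
  (Spearman). Reported coefficients and standard errors come from one
  full-data OLS fit. Ordinary least squares is the model family
  throughout: with ≤11 features and ~10^2 patients, regularising the
  final fit is unnecessary and would blur the coefficient±SE reporting;
  stepwise and robust variants are out of scope. Rank-deficient designs
  drop collinear columns (QR pivoting) with a warning rather than failing.
  When several models are compared, one shared fold assignment makes the
  comparison paired.

The p < 0.05 t-test on the full-data coefficients of the selected support
is reported but never used to prune further — post-selection inference on
a LASSO support is biased, so the package surfaces it as description, not
decision.

## The synthetic cohort generator

`generate_cohort` is first-class, tested code, not a fixture: it defines
the statistical structure every downstream guarantee is verified against.

* Latent activities $a_{ip} \sim N(0,1)$; sparse weights (density 0.2,
  scale 1); expression $x = Wa^\top + \varepsilon$,
  $\varepsilon \sim N(0, 0.5^2)$.
* Event times $T \sim \mathrm{Exp}(\lambda_0 e^{\sum_f \beta_f x_f})$ with
  $\lambda_0 = 0.02$/month, so the baseline median event-free survival is
  ~35 months; censoring $C \sim \mathrm{Exp}(0.008)$ truncated at a
  120-month administrative horizon (roughly a third of patients censored,
  typical of a 10-year follow-up registry). Exponential rather than
  Weibull: every acceptance quantity then has a closed form (e.g. the
  event fraction $\lambda_0/(\lambda_0+\lambda_c)$ under competing
  exponentials), and the choice only fixes the shape, not the screening
  machinery being tested.
* Proteomics is a subsampled (60% of genes), noisier copy of expression
  with logistic MNAR masking
  $P(\text{missing}\mid x) = 1/(1+e^{1.5(x - 0)})$, giving missingness
  monotone decreasing in intensity.
* Cohort defaults (300 patients, 100 genes, 5 pathways) are sized after a
  mid-sized tumour cohort screened over one pathway-scale gene panel.

One global seed expands into six fixed substreams (weights, activities,
noise, survival, proteomics noise, missingness), so planting a survival
effect does not perturb the expression draw — this is what makes the
two-pass "generate, inspect weights, regenerate with planted effects"
pattern in the end-to-end tests exact. The RNG is R's default
Mersenne-Twister; all cohorts are bit-reproducible under a fixed seed.

What the generator does **not** emulate: batch effects, library-size or
normalisation artefacts, copy-number or mutation structure, non-linear
gene–activity relations, informative censoring, and realistic gene
identifiers. Tests passing on these cohorts therefore demonstrate the
correctness and calibration of the *procedures*, not robustness of the
biology-side conclusions to the messiness of real TCGA/CPTAC-style data.

## Problem sizes and numerical choices

The test and acceptance suites run at deliberately chosen scales: oracle
equivalence on 200 random instances (n ≤ 30) against the survival
package; Yates monotonicity on 10^4 instances; null calibration on 1000
median-split cohorts at n = 60 and scan inflation on 200–300 of them;
cut-point recovery on 50–100 replicates at n = 400; imputation moments on
10^4 cells; regression coverage on 50 seeds at n = 1000; and the
end-to-end planted-pathway analysis on 50 seeds at n = 200, 60 genes, 3
pathways. These sizes make every Monte-Carlo bound comfortably stable
while keeping a full run in minutes on one core.

Degenerate inputs never crash the screen: constant features, all-censored
cohorts, features with fewer than 10 observed patients, and zero-variance
log-rank tables all produce flagged rows with p = 1. A group with zero
observed events yields an infinite log2 hazard ratio with a one-sided
confidence bound (the finite side computed with the zero count replaced
by 0.5) and a degeneracy flag. Ties in the scan are resolved
deterministically, and `V = 0` log-rank instances return p = 1 with a
warning rather than NaN.

## Orchestration

`run_pipeline()` executes simulate/load → gene screen → proteomics prep →
protein screen → pathway scoring → score-survival → model fitting and
comparison under one config and seed, and returns a report in which every
stage appears exactly once with a reproducible content digest. The
exported functions are the package's interface; the pipeline function is
a convenience wrapper over exactly those functions, and every
intermediate it writes is a plain tab-separated or JSON file.
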