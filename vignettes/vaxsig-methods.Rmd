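---
title: "Methods: from innate responses to antibody-response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from innate responses to antibody-response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific question

Adjuvanted vaccines differ widely in the innate immune response they
trigger in the first days after injection, and that early response appears
to shape the antibody response months later. This package implements a
systems-vaccinology pipeline that asks, for a five-arm adjuvanted
vaccination study (AS01B, AS01E, AS03, AS04, Alum), whether the innate
response measured one day after the second dose — the per-participant log
fold change of gene expression, of eight serum cytokines, and of
C-reactive protein (CRP) — predicts the magnitude and quality of the
antibody response at the peak (D60), persistence (D360), and
post-challenge (D390) timepoints, and which innate features carry that
prediction.

The clinical data the workflow was designed around are access-restricted,
so the package ships a seeded synthetic-study generator with a known
ground truth. Every stage is exercised and tested against that generator;
all statements below about what the pipeline recovers refer to synthetic
data, not the trial.

## Pipeline stages

1. **Data cleaning.** Probe-level expression is collapsed to gene level by
   keeping, per gene symbol, the probe with the maximum mean expression;
   probes without a symbol are discarded. Rows with interquartile range
   (IQR) at or below 0.75 are removed (strictly greater survives). Serum
   analyte values below their assay detection limit are flagged censored
   and replaced by draws from a truncated normal distribution.
2. **Fold change.** All values are analysed as post-minus-pre differences
   of log-scale measurements (gene expression on log2, cytokines/CRP log2,
   serology and total Ig log10 when raw).
3. **Module scoring.** Per-sample enrichment of blood transcriptional
   modules (read from GMT, filtered to 5–500 expressed members) is scored
   with a gene-set variation statistic (below).
4. **Integration.** Module scores and analyte log fold changes form the
   innate feature table; participants missing more than 50% of innate
   features are dropped (exactly 50% is kept). Antibody features of one
   timepoint are merged, the table is z-scaled, and remaining missing
   cells are imputed with K-nearest neighbours (K = 10).
5. **Prediction.** Every antibody feature at every timepoint is predicted
   from the innate features with a nested cross-validated LASSO and a
   random forest over the same 80:20 outer split plan, and gated for
   predictability.
6. **Ranking.** LASSO selection counts and forest permutation importances
   are corrected for predictor correlation clusters, dense-ranked,
   averaged across the two methods, standardised per antibody feature, and
   combined into top-k unions across features and timepoints.
7. **Association and classification.** Descriptive analyses (module
   K-means clusters, Pearson correlation maps, PCA with variable
   contributions, pairwise Wilcoxon tests with Benjamini–Hochberg
   adjustment) and a penalised logistic classifier separating the
   AS01/AS03-like arms from the AS04/Alum-like arms.

## The enrichment statistic

For gene $i$ with expression $x_{ij}$ across samples $j = 1..n$, a
Gaussian-kernel smoothed empirical CDF is evaluated at each sample,

$$\hat z_{ij} = \frac{1}{n}\sum_{k=1}^{n}
  \Phi\!\left(\frac{x_{ij}-x_{ik}}{h_i}\right), \qquad h_i = s_i/4,$$

with $s_i$ the per-gene standard deviation (a zero-variance gene
contributes a flat 0.5 and is logged). Within each sample, genes are
ranked by decreasing $\hat z$, ranks are converted to the symmetric
statistic $|p/2 - r|$ (up-weighting both tails), and a weighted
Kolmogorov–Smirnov random walk runs down the ranked list: in-set steps
add the symmetric statistic (exponent $\tau = 1$), out-of-set steps are
uniform. The default score is the maximum positive deviation of the walk
minus the magnitude of its maximum negative deviation (the
difference-of-extremes variant); the signed maximum-deviation variant is
available via `max_diff = FALSE`. Scores lie in $[-1, 1]$. Ties in the
sample-wise ranking are broken by gene order, which makes the scorer
deterministic and row-permutation invariant up to exact ties. The test
suite checks the vectorised scorer against an independent literal
implementation of these formulas to $10^{-8}$ on random instances.

## Numerical and design choices

- **IQR convention.** Quantiles use linear interpolation (type 7), the
  default of the R environment the workflow targets; the type is an
  argument of `iqr_filter()`.
- **Limit-of-quantification imputation.** Censored entries are drawn from
  Normal(threshold/2, 1) truncated to `[lower, threshold]`. A nominal
  lower bound of 1 is impossible for the 0.822 pg/mL cytokine cut-offs,
  so the lower bound is 1 when the threshold exceeds 1 and 0 otherwise;
  the fallback is logged whenever used. Draws use the inverse-CDF method
  and are reproducible under a seed; the empirical mean is tested against
  a numerically integrated truncated-normal mean.
- **KNN imputation.** Distances are Euclidean over co-observed features
  computed on the frozen input (imputed values never feed later
  distances); neighbours are weighted by $e^{-d}$; ties are broken by
  column order. z-scaling precedes imputation, reproducing the stated
  order of the source workflow.
- **Scaling leakage.** The full integrated table is z-scaled once before
  modelling, again reproducing the source order of operations even though
  it leaks scale information across CV splits; `integrate_features()` has
  a `scale_within_train` switch for callers wanting leakage-free scaling.
- **LASSO penalty path.** 100 penalties, log-spaced by glmnet from
  $\lambda_{max}$ down to $0.01\,\lambda_{max}$ (glmnet's own $n < p$
  default). The deeper $10^{-4}$ tail was considered and dropped: it only
  adds near-saturated fits that the cross-validated minimum never selects
  and roughly doubles the inner-loop cost.
- **Inner-loop penalty rule.** The description "the penalty corresponding
  to the average minimum cross-validated MSE over all 10 runs" is read as:
  average the ten 5-fold CV error curves over a shared grid, then take the
  arg-min of the averaged curve (rather than averaging ten per-run
  penalties). Classification uses the binomial deviance as the error.
- **Forest engine and tuning.** Forests use `ranger` with permutation
  importance scaled by its standard error — the %IncMSE analogue for
  regression and mean decrease in accuracy for classification. `mtry` is
  tuned per outer training set by stepping from the default (p/3
  regression, sqrt(p) classification) by factor 1.5 while the relative
  out-of-bag improvement exceeds 0.01, with 50-tree tuning forests (the
  customary small tuning default); the final forest has 1000 trees.
- **Predictability gates.** Regression: mean training deviance ratio
  $\ge$ 0.5 (LASSO) or mean OOB explained variance $\ge$ 0.5 (forest) —
  the either-method rule. Classification: mean balanced accuracy strictly
  above 0.5. Test R² is $1-\mathrm{SSE}/\mathrm{SST}$ about the test mean
  and may be negative. Repeats with a degenerate training response
  (constant y, or a missing class) are skipped and excluded from means: a
  constant response cannot be fit at all, so it is reported as a skip
  rather than a zero.
- **Correlation clusters.** Ward.D2 on the distance $1 - r$, cut at
  height $1 - 0.8$. Because Ward heights are not correlations, every
  cluster is post-validated (minimum pairwise $r > 0.8$) and split
  recursively where violated; constant features become singletons with a
  warning. The representative is the member with the largest IQR, ties by
  name.
- **Ranking.** Correction (within-cluster averaging of selection counts
  and importances) precedes ranking. Predictors never selected by the
  LASSO share the worst dense rank through the count-0 tie. Standardised
  ranks use the population SD (divisor n); standardisation happens within
  each antibody feature before the top-k union is taken.
- **W1 avidity labels.** W1 < 5 is labelled "high_avidity", following the
  source workflow's literal class assignment, although higher W1 values
  elsewhere denote higher avidity; because the intent is ambiguous the
  labels are arguments of `fit_w1_classifiers()`. In ordination mode W1
  is reverse-scaled (multiplied by −1) so that higher means higher
  avidity.
- **Classifier comparison.** The null model is the majority-class rate;
  the package adds a one-sided binomial test of the pooled test-set
  correct count against that rate (the source workflow reports accuracies
  without naming a test). The partial-least-squares variant of the
  classifier is out of scope.
- **Group tests.** `wilcox.test()` with R defaults (exact when both
  groups are below 50 and tie-free, normal approximation with tie
  correction otherwise); BH adjustment is applied across the entire
  result set.

## The synthetic-study generator

`sim_config()` / `simulate_study()` emulate the study design: five arms of
15/19/25/19/20 participants (98 total), plus `n_dropout` extra
participants generated to exceed the 50% innate-missingness filter — so
the configured arm sizes are exactly what survives filtering. Gene log
fold changes are built from per-module latent factors,
$x = \sqrt{\rho}\,L + \sqrt{1-\rho}\,\varepsilon$, the simplest structure
with controllable pairwise within-module correlation $\rho$ (default
0.7). Ten planted modules are up-shifted by 0.5 latent SD in the
AS01/AS03-like arms and ten counter-signal modules down-shifted
(NK-like), with CRP, IP-10 and IL-6 carrying the largest analyte post/pre
shifts. Analytes are generated on raw scale as lognormal values because
the censoring rules act there; antibody features are generated directly
on analysis (log) scale.

Antibody features are linear in the planted module latents:
$y_{ft} = a_t \sum_m w_{fm} L_m + \epsilon$, with attenuation
$a = (1.0, 0.3, 0.9)$ at D60/D360/D390 reproducing, qualitatively, the
drop in predictable features at the persistence timepoint. The noise SD
solves for a configured population R² (default 0.7 at $a=1$) using the
latent covariance implied by the group shifts, so ordinary least squares
on the true latents recovers the planted coefficients — a calibration the
test suite verifies. W1 is generated continuous around the class
threshold 5 so both avidity classes are present at every timepoint.

What the generator does **not** emulate: probe-level microarray structure,
batch or array effects, non-linear innate–antibody links, heavy-tailed or
skewed antibody distributions, assay floor effects at late timepoints, and
reactogenicity or cellular phenotypes. Passing tests therefore demonstrate
that the pipeline recovers planted linear structure under realistic
dimensions, correlation and missingness — not that it would recover the
trial's specific biology.

## Problem sizes used by the test suite

The statistical batteries run at the study's dimensions (n = 98
participants, 103 modules + 9 analytes = 112 predictors) with repeat
counts chosen as a practical desk-scale compromise: the noiseless-signal
and cross-validation-hygiene checks use 100 outer splits; the pure-noise
gating battery uses 20 seeded runs at 25 outer splits; the
signature-recovery battery uses 5 seeded studies at 20 outer splits with
two driven antibody features per timepoint; the full-run determinism check
uses 10 outer splits. The acceptance script (`scripts/acceptance.R`) runs
one full pipeline at 25 outer splits. Selection-frequency resolution
grows with the outer repeat count, so analyses of real data should use
the default 100.

## Known limitations

- The enrichment scorer is quadratic in the number of samples per gene
  (kernel CDF), which is fine for cohort-scale studies but not for
  thousands of samples.
- KNN imputation is an O(n² p) scan; adequate at cohort scale.
- The whole-table z-scaling follows the source workflow and leaks scale
  information across splits (see above); gates and test metrics are
  therefore mildly optimistic.
- Dense worst-rank ties for never-selected predictors compress the bottom
  of the LASSO ranking when selection is sparse.
- The adjuvant classifier reports pooled accuracy over overlapping test
  sets; the binomial p-value treats pooled predictions as independent and
  is anti-conservative under that overlap.
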