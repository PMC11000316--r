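---
title: "Methods: consensus selection and ensemble voting in pepvote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus selection and ensemble voting in pepvote}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepvote)
```

`pepvote` classifies case–control cohorts that combine a small clinical
block with a large block of mass-spectrometry peptide intensities, and
reports which features a *consensus* of selection methods considers
relevant. This vignette documents the statistical procedure, the choices
behind each default, what the synthetic cohort generator does and does not
emulate, and known limitations.

## The data model

A `feature_table` is a samples × features numeric matrix with a binary
diagnosis label encoded BPH = 0 (benign control) and PCa = 1 (cancer case,
the positive class everywhere in the package). Features are tagged
`clinical_numeric`, `clinical_categorical` or `peptide`; missing cells are
`NA` internally and the `NaN` literal on disk, because that is how these
cohort exports are commonly delivered. Labels are normalized
case-insensitively (`"PCA"`, `"pca"`, `"PCa"` are the same class); any
other label string is a data error rather than a third class, since silent
coercion of a typo into a new class is the worse failure mode.

## Preprocessing

The chain is: drop irrelevant columns → drop sparse rows, then sparse
columns → encode categoricals → impute → min–max scale.

* **Sparsity thresholds.** A sample or feature is dropped when more than
  half of its cells are missing (`sample_max_missing_frac = 0.5`,
  `feature_max_missing_frac = 0.5`). "More than half" is a conventional
  reading of "too many missing values"; both fractions are configuration
  parameters, and everything dropped is recorded in a log attribute.
* **Imputation.** The default replaces a missing cell with the mean of the
  same feature *within the same diagnosis class*. For markers like
  prostate gland volume, whose class means differ by tens of millilitres,
  class-conditional means are far less distorting than a global mean. The
  operation is idempotent and preserves observed class means by
  construction. A (feature, class) pair with no observed value falls back
  to the global mean with a warning; a feature with no observed value at
  all is an error.
* **Leakage policy.** Imputation and scaling are fitted once on the full
  labelled table by default — the classical single-fit workflow this
  package mirrors. That uses label information before cross-validation,
  which optimistic-biases CV estimates; `cv_config(fold_safe_preprocessing
  = TRUE)` refits the imputation means and min–max ranges inside each
  training fold for a statistically clean estimate. At prediction time
  labels are unknown, so held-out imputation always uses the stored global
  training means (`apply_preprocess(use_labels = TRUE)` exists for exact
  replay on labelled data).
* **Categoricals** map to ordinal integer codes `0..(L-1)` in sorted level
  order — plain numeric recoding, not one-hot; the mapping is stored and an
  unseen level at transform time is an error.
* **Scaling.** `(x − min)/(max − min)` per feature with training ranges; a
  constant feature maps to 0; held-out values are clipped to [0, 1]. The
  [0, 1] range matters downstream: the chi-square scorer requires
  non-negative inputs, and penalised-regression coefficient magnitudes are
  only comparable on a common scale.

No outlier rule is applied beyond the sparsity drops, and no
unit-of-measurement harmonization is attempted — both are left to the
analyst, who knows the assays.

## Consensus feature selection

Five rankers each nominate `k_per_method` features; a feature's consensus
score is the number of nominating methods (0–5). The default
`k_per_method = max(10, ⌈p/10⌉)` keeps the nominated sets comparable in
size — without comparable sizes the consensus count is not interpretable —
while scaling mildly with dimension.

* **Pearson filter.** Features are ranked by |r(feature, label)| and
  scanned greedily, discarding any candidate whose |r| with an
  already-kept feature exceeds 0.9, so only mutually low-correlated
  features are kept. The 0.9 cutoff discards near-duplicates (peptides of
  the same protein often correlate > 0.95) without pruning merely related
  markers; if pruning leaves fewer than k survivors the ranking is topped
  up, so every method returns exactly `min(k, p)` features. The
  correlation matrix itself is `R = C/√(Cii·Cjj)` from the feature
  covariance matrix; constant features get r = 0 off-diagonal (their
  correlation is undefined; 0 encodes "no evidence of association") and 1
  on the diagonal, with a warning.
* **Chi-square.** For non-negative features, observed counts are the
  per-class sums of the feature and expected counts split the feature
  total by class frequency; the statistic is `Σ(O−E)²/E` without
  continuity correction. This is the standard non-negative-feature scoring
  construction; no binning rule is imposed on the continuous intensities,
  and no p-values or multiplicity corrections are computed because only
  the ranking is used.
* **RFE.** Repeatedly fit a ridge-penalised logistic regression
  (`glmnet`, α = 0, λ = 1/n — unit-strength L2 on the mean
  log-likelihood) and remove the `rfe_step` features (default 1) with the
  smallest |coefficient|. Ridge logistic is used because the peptide block
  routinely has p ≫ n, where an unpenalised fit does not exist; ties in
  |coefficient| drop the later column so earlier features are kept
  deterministically. For very wide tables a larger `rfe_step` trades
  resolution of the elimination order for time.
* **Random forest.** 500 trees (seeded), mean-decrease-Gini importances
  normalized to sum to one, top k selected.
* **L1 logistic regression.** The lasso path is fitted and the first λ at
  which ≥ k coefficients are active is taken; features are ranked by
  |coefficient| there, topped up by order of entry into the path. Entry
  order is the natural lasso ranking when fewer than k coefficients ever
  activate.

**Threshold sweep.** For each candidate consensus threshold t (default 5
down to 1), the classifier battery is cross-validated on the features with
score ≥ t, and the t maximizing the *best single model's* mean AUC wins;
exact ties break toward the stricter threshold, preferring the smaller
panel. Best-model AUC is the objective because the workflow ultimately
deploys the best model (and AUC is the conventional model-choice metric in
this setting); the selected set is monotone non-increasing in t by
construction.

## Classification and metrics

The battery is LR (plain binomial GLM), decision tree (`rpart`, no depth
cap), KNN (5 neighbours, Euclidean), RBF-SVM (`e1071`, cost 1,
γ = 1/p, probability-calibrated), and random forest (500 trees). These
defaults are the conventional ones for each family; none are tuned, and
all are exposed through `model_spec()`. Evaluation uses stratified k-fold
cross-validation (k = 10 by default). Stratification deals each class
cyclically into folds after a seeded shuffle, the second class continuing
the deal where the first stopped, so per-fold class counts deviate from
proportionality by at most one and fold sizes by at most one. A fold whose
training part is single-class is skipped with a warning and metrics
average over completed folds.

Metrics, with PCa positive: Sensitivity TP/(TP+FN), Specificity
TN/(TN+FP), Accuracy, F1 = 2TP/(2TP+FP+FN), and AUC computed by the rank
(Mann–Whitney) formula with average ranks for ties — so a constant score
yields exactly 0.5, and any strictly monotone transform of the scores
leaves AUC unchanged. The test suite cross-checks the rank formula against
the trapezoidal area of the empirical ROC and against an established ROC
implementation.

## Voting

Hard voting returns the majority label of the five models; with five
voters and binary labels a tie is impossible, and for user-configured even
subsets the tie falls back to the soft-vote call. Soft voting computes
`score = Σ wᵢ pᵢ` with weights proportional to each model's mean CV
accuracy (uniform weights are available), calling PCa when score ≥ 0.5.
The ≥ convention must break the knife-edge case somewhere; breaking toward
the positive class favours sensitivity, the clinically conservative
direction for a cancer screen.

## The synthetic cohort generator

`generate_cohort()` emulates the two study designs the package targets:
a serum design (69 PCa / 74 BPH, 37 features) and an EPS-urine design
(67 PCa / 54 BPH, 1670 peptides), via `serum_spec()` / `urine_spec()`.

* **Clinical covariates** are drawn per class from truncated normals
  within the published per-class [min, max]. The published mean/sd/min/max
  of the strongly skewed PSA markers are mutually inconsistent with *any*
  normal truncated at those extremes (truncation at min 3.01 with sd 11.47
  necessarily drags the mean above 10.33), so the generator moment-matches
  the underlying (μ, σ) such that the *truncated* distribution reproduces
  the tabulated moments as closely as the family allows; for mildly
  truncated features (age, gland size, free PSA) the match is exact.
  `self_test()` therefore validates sample moments against the
  model-implied values, with tolerances scaled by the standard error.
* **Peptides** are log-normal (log-sd 0.5), the standard right-skewed
  model for MS intensities; per-peptide baseline abundances are population
  parameters drawn once from the spec seed, so training cohorts and
  hold-outs (`generate_holdout()`, disjoint sample stream) come from the
  same population. The planted informative subset (default 5) is shifted
  by `effect_size_d` log-standard-deviations (default d = 1.5, a strong
  but realistic discovery-grade marker) in the PCa class; all other
  peptides are identically distributed across classes.
* **Missingness** is MCAR at rate 0.1 in the gland-size and PSA columns —
  the columns where real exports are incomplete. Real missingness is
  likely not completely at random (e.g. ultrasound not performed for
  specific clinical reasons); MCAR is the deliberate simplification.
* The F/T ratio is sampled from its tabulated marginal by default even
  though it deterministically derives from the other two PSA columns in
  real data; `derive_ft_ratio = TRUE` switches to the exact quotient.
  Clinical features are otherwise independent within class, and no batch
  effects, censoring at assay limits, or peptide–peptide correlation
  structure are simulated.

Consequently, passing tests on synthetic cohorts demonstrate that the
pipeline recovers planted signal of the stated effect size under clean
conditions, that its metrics are calibrated at the null, and that it is
deterministic — not that real serum or urine cohorts will reach any
particular AUC. Synthetic performance is typically *higher* than published
cohort performance because the generator's features are independent and
its effects clean; that gap is expected and not a defect.

## Numerical and reproducibility choices

* Determinism: every stochastic step (fold shuffles, forests, SVM
  probability calibration, KNN tie-breaks, the generator) is seeded; the
  pipeline fans one global seed out to the stages with fixed offsets, so
  stages rerun in isolation reproduce the chained run and identical
  config + seed reproduces selection and prediction files byte for byte.
* Degenerate inputs: constant features normalize to 0 and correlate 0;
  empty hold-outs give empty reports; an all-missing feature or class is
  an explicit error, as are unknown labels, duplicate ids and non-numeric
  cells (named by row and column).
* Tolerances in the test suite: exact identities (confusion counts,
  majority votes) are asserted exactly; floating-point oracle equivalences
  (covariance vs correlation, rank-AUC vs trapezoid) at 1e-10; statistical
  properties use standard-error-scaled bands at fixed seeds.
* Problem sizes: simulation-based tests use cohorts of 100–200 samples
  and 10–100 peptides, and the acceptance script samples the urine-design
  peptide block down to 300 columns (elimination step 10); these sizes
  exercise the p ≈ n and p ≫ n regimes that matter while keeping runs
  reproducible in minutes on one core.

## Limitations

Binary classification only (the machinery would extend to multiclass, but
no such interface is exposed). No hyperparameter tuning, calibration
analysis, or stacking beyond the two voting rules. The default
preprocessing reproduces the classical full-data fit, with the leakage
caveat above. The chi-square scorer's class-sum construction is a ranking
heuristic, not a calibrated test. And the synthetic generator, by design,
cannot stand in for biological validation of any selected peptide.
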