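# pepvote

Consensus feature selection and ensemble voting for clinical-proteomics
case–control classification.

## The problem

In biomarker-discovery studies, mass-spectrometry peptide quantification
yields hundreds to thousands of intensity columns per patient, alongside a
handful of clinical covariates (age, prostate gland volume, total/free PSA
and their ratio in the prostate setting this package grew out of). The
analytical task is to separate cases (prostate cancer, PCa) from controls
(benign prostatic hyperplasia, BPH) and, just as importantly, to say *which*
features carry the signal — robustly, not as the idiosyncratic pick of one
selection algorithm.

`pepvote` implements that workflow for statisticians and bioinformaticians
working on tabular clinical + peptide data:

1. **Preprocessing** — dropping overly missing rows/columns, removing
   irrelevant columns, class-conditional mean imputation, ordinal encoding
   of categoricals, min–max scaling to [0, 1].
2. **Consensus feature selection** — five rankers vote on features: a
   Pearson redundancy filter, chi-square scoring, recursive feature
   elimination (RFE), random-forest Gini importance, and L1-penalised
   logistic regression. Each feature gets a *consensus score*
   `s(f) ∈ {0,…,5}` = the number of methods that nominated it; the score
   threshold is then chosen by cross-validated performance of the
   restricted panel.
3. **Classification** — logistic regression, decision tree, k-nearest
   neighbours, RBF support-vector machine and random forest, assessed by
   stratified 10-fold cross-validation on AUC, Accuracy, F1, Sensitivity
   and Specificity (PCa = 1 is the positive class; AUC is the rank
   [Mann–Whitney] statistic).
4. **Ensemble voting** — *hard* voting takes the majority of the five
   predicted labels; *soft* voting thresholds the weighted mean
   probability `Σᵢ wᵢ pᵢ ≥ 0.5`, with weights `wᵢ` proportional to each
   model's cross-validated accuracy.

Because real serum/urine cohorts of this kind are not publicly
deposited, the package ships a **synthetic cohort generator**
(`generate_cohort()`) that emulates the two published study designs —
a serum design (143 samples: 69 PCa / 74 BPH, ~37 features) and an
EPS-urine design (121 samples: 67 PCa / 54 BPH, ~1670 peptides) — with
class-conditional truncated-normal clinical covariates, log-normal peptide
intensities with a planted informative subset, and missingness in the
clinical columns. Every pipeline stage is testable against planted ground
truth.

## Worked example

```r
library(pepvote)

spec   <- urine_spec(n_peptides = 40, effect_size_d = 2, seed = 7)
cohort <- generate_cohort(spec)          # 121 samples, 45 features
fit    <- pepvote(cohort,
                  sel_cfg = selector_config(k_per_method = 8, seed = 7),
                  cv_cfg  = cv_config(k = 5, seed = 7))
summary(fit)
```

```
consensus feature selection
  chosen threshold: >= 5 of 5 methods
  selected features (8): ProstateGlandSize, TotalPsa, PsaFree, pep0001,
                         pep0002, pep0003, pep0004, pep0005

stratified cross-validation report
 model mean_auc mean_accuracy mean_f1 mean_sensitivity mean_specificity
    LR    0.999         0.983   0.984            0.969            1.000
    DT    0.871         0.851   0.870            0.867            0.827
   KNN    0.987         0.967   0.970            0.955            0.982
   SVM    0.997         0.976   0.978            0.970            0.982
    RF    0.999         0.975   0.977            0.970            0.982
best model by mean AUC: RF
```

The five planted peptides (`pep0001–pep0005`) and the genuinely
class-separated clinical markers are exactly the unanimous (score-5)
features; the sweep keeps the strictest threshold. Prediction on a fresh
hold-out uses both voting strategies:

```r
preds <- predict(fit, generate_holdout(spec, 12))
count_correct(preds, "hard")   # 12 of 12
count_correct(preds, "soft")   # 12 of 12
write_prediction_report(preds, "predictions.csv")
```

`coef(fit)` returns the normalized soft-vote weights, `plot(fit)` draws the
out-of-fold ROC curves per model.

File-based runs (`run_pipeline()`, or the stage functions
`stage_simulate()` … `stage_vote()`, or
`Rscript inst/scripts/pipeline.R run-all --config cfg.json --out dir`)
write a run directory with the selection JSON, CV report, ROC CSVs,
prediction CSV and a provenance manifest; identical config + seed
reproduces the selection and prediction files byte for byte.

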