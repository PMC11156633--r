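# calaudit

Calibration auditing and recalibration of deployed clinical risk models.

## The problem

A risk model deployed in routine care emits a predicted probability for
each admission; a gold-standard assessment later records whether the event
occurred. Calibration — the agreement between predicted probabilities and
observed event frequencies — decays after deployment and can decay
*differently across patient subgroups*, which turns a statistical defect
into a fairness problem: a group whose risk is systematically overestimated
receives more false alarms and misdirected clinical attention. `calaudit`
is for data scientists and clinical-ML teams who need to quantify that
miscalibration, test whether subgroups differ, repair the model by
recalibration, and verify the repair on a temporal hold-out.

## What it computes

The audit follows the hierarchical view of calibration:

* **Weak calibration** — the logistic calibration fit
  `logit P(y=1) = α + β·logit(p̂)`, ideally `(α, β) = (0, 1)`; a negative
  intercept means overestimated risk, a slope above 1 an underfitted risk
  distribution. Calibration-in-the-large (the intercept with `β` fixed at
  1) is reported alongside.
* **Moderate calibration** — Brier score (raw and scaled against the
  prevalence predictor), and the loess calibration curve summarized by
  `Eavg`/ICI (mean |curve − diagonal|) and `Emax` (maximum deviation).
* **Strong calibration** — the same curves and bundles within every
  subgroup level (gender, race, payor, hospital type, ...).
* **Discrimination** — Harrell's c-index (ties 0.5, rank-based `O(n log n)`)
  and sensitivity/specificity/PPV/NPV/accuracy at site-specific decision
  thresholds.
* **Recalibration** — recalibration-in-the-large (intercept only) and
  logistic recalibration (intercept and slope), fitted on the training
  sample, applied to both samples: `p̂′ = expit(α + β·logit(p̂))`.
* **Inference** — percentile bootstrap CIs for every metric and empirical
  two-sided bootstrap p-values for subgroup differences with add-one
  correction (`p ∈ [2/(B+1), 1]`, never exactly 0) and Bonferroni control.
* **Cohort assembly** — reduction of daily prediction/assessment events to
  one record per patient, temporal train/hold-out splits, and baseline
  tables with standardized mean differences (binary and
  Mahalanobis-multicategory).
* **Synthetic cohorts** — a generator with known subgroup-specific
  logit-scale miscalibration `(a_g, b_g)`, so every stage of the pipeline
  can be validated against ground truth.

## Worked example

Simulate a 50,000-admission cohort with the built-in gender-specific
miscalibration (intercepts −1.49 female / −0.88 male, slopes 1.42 / 1.40,
24% event rate), audit it, and recalibrate:

```r
library(calaudit)
rec   <- generate_cohort(synth_config(n = 50000, seed = 7))
train <- rec[rec$sample == "train", ]

fit_weak_calibration(train$p_hat, train$outcome)
#> Weak calibration (n = 37141 )
#>   intercept (joint fit): -1.1675
#>   slope     (joint fit): 1.3583
#>   CITL  (slope fixed 1): -1.0719
```

The pooled training sample recovers the blended truth: intercept −1.17
(risk overestimated overall) and slope 1.36 (risk distribution
underfitted). Logistic recalibration on the training sample transfers to
the hold-out period:

```r
m    <- fit_recalibration("logistic", train$p_hat, train$outcome,
                          fit_sample = "train")
hold <- rec[rec$sample == "holdout", ]
fit_weak_calibration(apply_recalibration(m, hold$p_hat), hold$outcome)
#> Weak calibration (n = 12859 )
#>   intercept (joint fit): 0.0023
#>   slope     (joint fit): 1.0049
#>   CITL  (slope fixed 1): -0.0013
```

and the gender gap in the *original* model is detected by the bootstrap
comparison (the intercept difference is real; the slope difference is not):

```r
res <- compare_groups(train$p_hat, train$outcome, train$gender,
                      c("Female", "Male"),
                      metrics = c("intercept", "slope"), reps = 199,
                      seed = 7)
res$intercept
#> intercept: Female - Male = -0.6009 (p = < 0.01; B = 199)
res$slope
#> slope: Female - Male = 0.0181 (p = 0.54; B = 199)
```

The full pipeline — every recalibration variant × sample × subgroup cell
with bootstrap CIs, pairwise comparisons, calibration curves and percentile
summaries — is one call, `run_audit(rec, audit_config(seed = 7))`, and
`export_tables()` writes `metrics.csv`, `comparisons.csv`, per-cell curve
CSVs and a full-precision `audit.json`. The same operations are available
from a shell:

```sh
Rscript inst/cli/calaudit.R simulate --seed 7 --n 50000 --output cohort.csv
Rscript inst/cli/calaudit.R audit --input cohort.csv --output-dir audit-out
```

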