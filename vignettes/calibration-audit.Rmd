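---
title: "Auditing the calibration of a deployed clinical risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the calibration of a deployed clinical risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calaudit)
```

## The problem

A risk model deployed in routine care emits a predicted probability
$\hat p$ for each admission; a gold-standard assessment later records a
binary outcome $y$. Even when the model discriminates well, its
probabilities can drift away from observed event frequencies — overall, or
selectively within patient subgroups, where miscalibration becomes an
equity problem: systematically overestimated risk in one group means more
false alarms and misallocated attention for that group. `calaudit`
implements the audit workflow for this situation: quantify miscalibration
along the established hierarchy, test whether subgroups differ, recalibrate
on a training period, and verify the repair on a later hold-out period.

## The calibration hierarchy

**Weak calibration.** The logistic calibration model regresses the outcome
on the logit of the prediction,

$$\operatorname{logit} P(y = 1) = \alpha + \beta \,\operatorname{logit}(\hat p),$$

with ideal values $\alpha = 0$, $\beta = 1$. Under the standard
convention a *negative* intercept indicates overestimated risk and a slope
above 1 an underfitted (too narrow) risk distribution.
`fit_weak_calibration()` reports the joint fit $(\alpha, \beta)$ and, in
the same object, calibration-in-the-large (CITL): the intercept re-fitted
with $\beta$ fixed at 1, the logit prediction entering as an offset. Both
intercept conventions circulate in applied reports — the joint-fit
intercept moves when the slope does, CITL does not — so both are surfaced
and labeled rather than conflated.

**Moderate calibration.** A loess curve of outcome on prediction estimates
the observed event frequency at each predicted risk. Its agreement with the
diagonal is summarized by the mean absolute deviation Eavg (also called the
integrated calibration index, ICI) and the maximum absolute deviation Emax,
both over the observed predictions (`eavg_emax()`). The Brier score
$\frac 1n \sum (\hat p_i - y_i)^2$ is reported raw, together with a scaled
version $1 - B/\bar y(1-\bar y)$ against the constant prevalence predictor.
The raw score is the primary value; scaling conventions are ambiguous
across reports, so the scaled variant is always explicitly labeled
"higher is better".

**Strong calibration.** Moderate calibration within every covariate
subgroup. The audit approximates it the practical way: per-subgroup curves
and metric bundles (`run_audit()`), not a formal joint test.

**Discrimination** is audited alongside: Harrell's c-index (ties counted
0.5, computed by the midrank identity in $O(n \log n)$, which equals the
pairwise definition exactly) and sensitivity/specificity/PPV/NPV/accuracy
at the deployment's decision threshold. Thresholds may differ by site;
records are then judged each at its own site's cutoff.

## Recalibration

Both updating methods act on the logit scale and are fitted on the
training sample only, then applied to training and hold-out samples alike:

* *recalibration-in-the-large*: slope fixed at 1, intercept = CITL;
* *logistic recalibration*: intercept and slope freely estimated.

`apply_recalibration()` computes
$\operatorname{expit}(\alpha + \beta\,\operatorname{logit}(\hat p))$. For
$\beta > 0$ this is strictly increasing, so rank-based discrimination is
provably unchanged — the audit asserts this invariance rather than assuming
it. Two fixed points pin the implementation down: refitting the weak
calibration on logistically recalibrated training data returns $(0, 1)$ to
optimizer tolerance, and CITL after recalibration-in-the-large is 0 while
the joint-fit slope is exactly unchanged. Subgroup cells are evaluated
under the *pooled* recalibration model — per-subgroup refits would trivially
zero every subgroup's miscalibration and hide exactly the heterogeneity the
audit is looking for. A direct consequence worth keeping in mind when
reading reports: when subgroups are truly differentially miscalibrated, the
pooled logistic recalibration restores the *overall* hold-out cell to
$(0, 1)$ but subgroup cells legitimately remain offset in both directions.

## Inference

Confidence intervals are percentile bootstrap intervals (default
$B = 100$ replicates, resampling records with replacement). Subgroup
differences use *unpaired* resampling — the two groups are disjoint patient
sets — and the empirical two-sided p-value

$$p = \min\!\Big(1,\; 2\min\big(m_{\le}, m_{\ge}\big)\Big), \qquad
m_{\le} = \frac{1 + \#\{D^*_b \le 0\}}{B + 1},$$

with the add-one correction, so $p \in [2/(B+1), 1]$ and is never exactly
0 (reports that print "p = 0" are showing a resolution floor, which this
package displays as "< 2/(B+1)"). Multiplicity is controlled by Bonferroni
($\alpha/k$ over the $k$ tests actually performed) or by a fixed external
threshold such as 0.001. Note the interaction between the two choices: at
$B = 100$ the smallest attainable p-value is $2/101 \approx 0.02$, so a
0.001 threshold is unreachable by construction; detecting at that threshold
requires $B \ge 2000$. The audit defaults keep $B = 100$ for interval
width, and the validation suite uses larger $B$ where it tests rejection
behavior. Percentile intervals were chosen over BCa deliberately: at
$B = 100$ BCa's acceleration estimate is unstable, and the percentile
method is the transparent default.

## The synthetic cohort generator

No patient-level data ship with the package; the generator provides ground
truth instead. Each record belongs to a group $g$ with truth
$(a_g, b_g, \mu_g, \sigma_g)$. A latent score
$z \sim \mathcal N(\mu_g, \sigma_g)$ yields the deployed model's prediction
$\hat p = \operatorname{expit}(z)$, while the true event probability is
$\operatorname{expit}(a_g + b_g z)$. By construction the within-group
logistic calibration fit has population intercept $a_g$ and slope $b_g$ —
the generator's truth *is* the estimand, which is what makes parameter
recovery, fixed-point and power tests meaningful.

Defaults emulate a diverse five-hospital inpatient malnutrition-screening
cohort: ~49.9% female, race mix of roughly 6.6% Asian / 29.6% Black /
28.3% other / 35.4% White, five facilities with decision thresholds spread
over 0.44–0.58, a 24% event rate, and a 74.2% / 25.8% train-to-holdout
split with admission dates in 2021–2022 (train) and 2023 (hold-out). The
default miscalibration truth is gender-specific — intercepts $-1.49$
(female) and $-0.88$ (male) with slopes 1.42 and 1.40 — magnitudes of the
kind observed when a deployed screening model overestimates risk more
strongly in one gender. The latent-score spread $\sigma = 1.5$ was chosen
once as a realistic dispersion for a screening model whose scores span
roughly 0.05–0.95; group means $\mu_g$ are then *solved*, not tuned:
`solve_mu_for_prevalence()` root-finds the $\mu$ whose numerically
integrated event rate matches the target prevalence to $10^{-6}$.

Two generation modes exist because per-attribute truths cannot be jointly
exact: `single_attribute` ties the truth to one attribute's levels (used by
every exact-recovery test), while `composite` combines per-level deviations
additively on intercepts and multiplicatively on slopes across attributes —
a documented approximation for producing jointly varied cohorts.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: correlation between attributes (they are drawn
independently), the feature structure behind the score (scores are drawn,
not computed from covariates), temporal drift within a sample,
repeat admissions, and verification/workflow bias, in which the
model's own predictions influence who gets assessed and hence which labels
exist. The longitudinal generator reproduces that workflow's *suppression
mechanics* (a positive assessment permanently suppresses predictions; a
negative one suppresses them for three days) so the reduction to one
analysis record per patient can be tested, but it does not model
prioritization by predicted risk.

## Cohort assembly

`reduce_admissions()` turns daily prediction and assessment events into one
record per patient: the maximum predicted probability among predictions
followed by at least one assessment, paired with the first assessment on or
after that prediction. Same-day assessments count as "after" — at daily
granularity, excluding them would discard most real pairings. When the
globally maximal prediction has no later assessment, the maximum is taken
over predictions that do (rather than excluding the patient). Patients with
no assessment, or none after any prediction, are excluded and counted.
The analysis unit is the patient identifier; multiply-admitted patients are
not split into separate admissions.

Baseline tables (`summarize_baseline()`) display medians and IQRs for
continuous variables but compute standardized mean differences from means
and standard deviations, the standard convention; multicategory SMDs use
the Mahalanobis form $\sqrt{T' S^{-1} T}$ over $k-1$ categories with $S$
the average multinomial covariance, which is invariant to category order
and to the dropped category. Missing values get their own table row and are
excluded from SMDs; nothing is imputed, since the calibration analyses need
only $(\hat p, y)$.

## Numerical choices

* Probabilities are clipped to $[10^{-6}, 1 - 10^{-6}]$ before any logit.
* Calibration fits use a damped Newton solver converging on the *score*
  (max component $< 10^{-8}$), with step-halving and a $|\hat\theta| > 50$
  separation guard that raises an explicit non-convergence error.
* Loess: span 0.75, degree 1, tricube weights, evaluated at the observed
  predictions, fitted values clipped to $[0, 1]$. The local regression is
  computed exactly at every point for $n \le 2000$ and via the standard
  interpolating surface above that (accurate here to a few parts in
  $10^{4}$, while keeping bootstrapped curve metrics tractable at cohort
  scale). The smoother settings are configurable; none were dictated by the
  audited deployment, which is why the defaults follow common practice.
* Ties in the c-index earn 0.5; positive calls use $\hat p \ge$ threshold
  (ties called positive).
* Bootstrap quantiles are type-7; per-cell bootstrap seeds derive
  deterministically from the master seed and the cell identity, so reports
  are byte-identical across runs and independent of evaluation order.
* Metrics with zero denominators (e.g. PPV when nothing is called
  positive) are returned as `NA` and named in an `undefined` field, never
  silently reported as 0.
* Date splits are inclusive-left: the boundary date belongs to training.

## Validation problem sizes

The shipped validation suite exercises: exact SMD reproduction from a
printed reference baseline table; parameter recovery at $n = 100{,}000$
(tolerance $\pm 0.05$); fixed points at optimizer tolerance; c-index
against a brute-force pairwise oracle on 100 random tied instances
($n \le 500$); the smoother against an independently coded tricube
weighted-least-squares oracle on a 200-point fixture (tolerance
$10^{-8}$); bootstrap size (400 null repeats at $n = 2000$ per group,
$B = 199$) and power (50 repeats at $n = 5000$ per group against the
built-in gender gap); and a full simulate-then-audit run at $n = 50{,}000$
with $B = 100$. These sizes are the package's chosen compromise between
Monte-Carlo resolution and a test suite that runs in minutes.

## Known limitations

* The composite generation mode is approximate by design; exact recovery
  holds only in single-attribute mode.
* Percentile intervals can undercover for strongly skewed metrics at
  $B = 100$; raise `reps` when interval endpoints matter.
* The audit reports subgroup cells under the pooled recalibration model
  only; per-subgroup recalibration is a modeling decision out of scope.
* Eavg/Emax depend on the smoother settings; values from different spans
  or degrees are not comparable.
* No isotonic or spline recalibration, no model refitting, no
  decision-curve analysis.
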