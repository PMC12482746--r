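---
title: "Validating cisplatin-AKI risk scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating cisplatin-AKI risk scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cakival)
```

## What the package computes

`cakival` validates two points-based risk scores for cisplatin-associated
acute kidney injury (C-AKI) on a cohort other than the one they were
developed in. External validation asks two distinct questions.
*Discrimination*: does the score rank patients who develop the outcome
above those who do not (AUROC)? *Calibration*: do the predicted absolute
risks match observed event rates (calibration-in-the-large, calibration
slope, and the decile calibration curve)? The Brier score summarises
both. Because treatment decisions act on absolute risk, a discriminating
but miscalibrated model can still harm — which decision curve analysis
makes explicit — and logistic recalibration is the minimal repair: refit
an intercept and a slope, touch nothing else.

## Outcomes

All labels derive from the serum-creatinine trajectory within 14 days of
cisplatin exposure (day 0 is baseline; post-exposure days are 1..14):

* **C-AKI**: rise ≥ 0.3 mg/dL from baseline, or ≥ 1.5-fold rise.
* **Severe C-AKI**: ≥ 2.0-fold rise, or initiation of renal replacement
  therapy (RRT) within the window, regardless of creatinine.

These are KDIGO-anchored with one deliberate deviation: the 0.3 mg/dL
criterion is applied over the whole 14-day window rather than within
48 h, matching how the Motwani model's outcome was defined. All
comparisons are inclusive (a ratio of exactly 2.0 is severe) and are
evaluated with a 1e-9 numerical tolerance so that values landing exactly
on a printed decimal boundary (0.40 → 0.60 is a 1.5-fold rise) classify
positive despite binary floating point. A patient with no in-window
creatinine and no RRT raises a dedicated `caki_unassessable` condition
rather than silently labelling negative. Urine-output criteria and
injury beyond 14 days are out of scope.

## Scores and probability mappings

Point tables follow the published models exactly; totals live on a
half-point grid (Motwani 0–9.5, Gupta 0–22.5, or 0–21.5 without
magnesium). Two reading conventions matter and are enforced in code and
tests:

* Printed integer ranges such as dose "101–150 mg" are read as
  (100, 150]: a dose of 100.5 mg joins the 101–150 bin. The same applies
  to hemoglobin 11.95 g/dL (bin 11.0–11.9).
* Albumin and hemoglobin are treated as g/dL. The point table's header
  says mg/dL, but the companion cohort description reports albumin in
  g/dL and the bin edges (3.3–3.8, 11.0–12.0) only make clinical sense
  in g/dL.

The Motwani score maps to probability through its published development
constants — risk 0.04 at score 0, odds ratio 1.49 per point — so
`motwani_probability()` is fully determined. The Gupta simple score has
no published per-score probabilities; its companion primary model uses a
cubic spline. The original spline coefficients are not published, so the
default mapper refits that *shape* on a designated reference cohort: a
logistic regression of the outcome on a restricted cubic spline of the
score with 4 knots at score quantiles 0.05/0.35/0.65/0.95 (standard
knot-placement practice). The mapper slot is pluggable — any function or
fitted `caki_mapper` can be supplied, so published coefficients can be
dropped in — but it must be monotone: if the spline fit wiggles (weak
signal, small n), the fit falls back to the strictly monotone
linear-logistic form. This guarantees AUROC computed on mapped
probabilities equals AUROC on raw points, which in turn makes the
pre-vs-post-recalibration AUROC identity exact.

## Estimators

* **AUROC** is the pairwise concordance probability with ties credited
  0.5, computed via rank sums (O(n log n)); the test suite checks it
  exactly against a brute-force O(n²) oracle up to n = 500 and against
  an independent ROC implementation.
* **Calibration-in-the-large** is the intercept of a maximum-likelihood
  logistic regression of outcome on logit(p̂) with the slope fixed at 1
  (offset formulation). Negative values mean overestimation.
* **Calibration slope** is the logit(p̂) coefficient in the
  unconstrained logistic refit; 1 is ideal, < 1 means predictions too
  extreme. Probabilities are clipped to [1e-9, 1 − 1e-9] before the
  logit, with a warning.
* **Brier score** is mean (p̂ − y)²; a constant prediction at prevalence
  π has expectation π(1 − π), the "variance floor" a weak model cannot
  beat.
* **Bootstrap inference**: patients are resampled with replacement,
  unstratified; each metric is recomputed per replicate and reported as
  the bootstrap mean with percentile 2.5/97.5 bounds (1,000 replicates
  by default). Replicates whose resample has a single outcome class are
  redrawn and counted. AUROC differences between models use the paired
  patient-level bootstrap; the two-sided p-value is
  2·min(P(Δ ≤ 0), P(Δ ≥ 0)), floored at 1/n_boot.

## Recalibration

`logistic_recalibrate()` fits outcome on the **raw score** — not on the
logit of the mapped probability. For the Motwani model the two
parameterisations are affinely equivalent; for the Gupta spline mapper
they are not, and the raw-score form is the one the validation workflow
specifies. Exactly two parameters are ever fitted. Evaluated on the
cohort it was fitted to, the refit identity makes CITL 0 and slope 1 to
machine-level tolerance, and — because the mapping is strictly monotone
for positive slope — AUROC is unchanged to 1e-12. Fewer than 10 events
(or non-events) triggers a warning, fewer than 2 a refusal; separation
is detected and named. Post-recalibration bootstrap supports two
readings: the default bootstraps the once-fitted model (the
apparent-validation reading, matching bootstrap-mean slopes of ≈ 1.0);
`boot_refit = TRUE` refits the recalibration inside every replicate,
which re-centres the apparent slope at exactly 1 per replicate and so
collapses its interval — the default is the reading consistent with
reported post-recalibration slope CIs of non-trivial width.

## Decision curves

Net benefit at threshold t classifies positive when p̂ ≥ t (inclusive)
and is TP/n − (FP/n)·t/(1 − t). Treat-all equals π − (1 − π)t/(1 − t)
(crossing zero at t = π), treat-none is 0, and a perfect predictor
attains π everywhere. The default grid is 0.005–0.50 in steps of 0.005 —
covering the clinically discussed range (net harm of the unrecalibrated
models appears above roughly 12.5%) without extrapolating into
thresholds no clinician would use for prophylaxis decisions. Regions of
net harm are flagged per strategy.

## Imputation

Missing baseline labs are filled by regression-based *single*
imputation: per incomplete lab, an OLS fit on the always-complete
covariates (age, sex, dose, baseline creatinine, hypertension, diabetes,
smoking) using complete cases, then deterministic conditional-mean
fill-in, clipped to positive support, with per-cell provenance flags.
No stochastic residual is drawn and no multiple imputation is pooled —
the validated workflow used deterministic regression imputation, which
has comparable predictive performance in prediction-model settings.
Outcome labels are deliberately excluded from the predictor set so
imputation cannot leak outcome information into the scores. Imputation
is idempotent and never alters an observed cell. The pipeline imputes
the already-selected baseline values; baseline selection itself (most
recent value within 30 days) is upstream of this package's inputs and is
emulated, not re-implemented, by the generator.

## The synthetic cohort generator

Raw patient data for such validations are rarely shareable, so the
package ships a seeded generator that emulates the reference cohort's
statistical structure. It is first-class, tested code — not a test
fixture — and its defaults are frozen as the study conditions:

* n = 1,684 patients; age from a truncated skew-normal on [18, 95]
  solved to quantiles 58/66/71 years (the closest attainable fit in that
  family is within 0.7% per quantile); all other continuous covariates
  log-normal with median/IQR matching the reference description (dose
  110 (90–130) mg, creatinine 0.75 (0.63–0.87) mg/dL, albumin 3.9
  (3.5–4.2) g/dL, hemoglobin 12.5 (11.3–13.6) g/dL, WBC 5.99
  (4.64–7.56)·10³/mm³, platelets 256 (203–313)·10³/mm³, magnesium 2.05
  (2.00–2.10) mg/dL).
* Binary covariates: male 66.7%, diabetes 12.1%, smoker 64.8%;
  hypertension 35.3% with a positive age association (+0.04 log-odds per
  year), since hypertension prevalence rising with age is the one
  dependence too clinically basic to omit. All other covariates are
  generated independently — the reference publication gives no
  correlation structure.
* Lab missingness: albumin 6.0%, magnesium 61.2%, platelets 0.1%, WBC
  0.7%; missing-completely-at-random by default, with an optional
  missing-at-random mode (mask probability increasing in observed age)
  for stress-testing the imputer.
* Outcomes: a true class (none / stage 1 / severe) is sampled *before*
  the trajectory, from a nested logistic model on the complete-data
  Gupta score — C-AKI with per-point log-odds 0.173, then severe given
  C-AKI with per-point log-odds 0.112 — with intercepts solved by root
  finding on the realized cohort so expected prevalences hit the targets
  (11.0% and 2.1%) exactly, at any slope or drift setting. The slopes
  were calibrated once, at n = 120,000 through the full
  mask→impute→score pipeline, so the *post-imputation* Gupta score's
  AUROC matches the reference validation (≈ 0.616 for C-AKI, ≈ 0.674
  for severe), and then frozen. Sampling truth first lets the generator
  emit a hidden truth table, which is what makes calibration-drift and
  prevalence recovery assertable in tests.
* Trajectories: baseline plus creatinine at days 3, 7 and 14, with the
  peak at day 7 placed uniformly inside the class-consistent interval
  (below min(b + 0.3, 1.5b) for non-events; between that threshold and
  2b for stage 1; in [2b, 3b] for severe) and flanking days
  interpolating toward baseline. Class intervals keep a 1e-7 relative
  margin from the thresholds so labelling reproduces the sampled class
  for 100% of patients at any seed. The reference workflow does not
  describe sampling cadence; three post-dose points is a typical
  inpatient monitoring pattern.
* RRT is assigned only within the severe class (RRT implies stage ≥ 2 by
  definition), at rate 0.10 — the reference does not report its RRT
  count; most stage ≥ 2 C-AKI is managed without dialysis, so a small
  value is the realistic choice.
* One row per patient (first cycle): the reference cohort description
  implies one record per patient, and repeat cycles or time-varying
  dosing are not modelled. The eligibility cascade (age < 18,
  daily/weekly regimens, missing outcome data) is likewise not emulated:
  the generator emits eligible patients only.

What the generator deliberately does *not* emulate — and hence what
passing tests do **not** show about real data: inter-lab correlations
beyond age–hypertension, measurement and assay noise in creatinine
(Jaffe vs enzymatic), informative missingness tied to unobserved
severity, repeat dosing, and the magnitude of the magnesium item's
contribution to discrimination (61% of magnesium values being imputed
attenuates it here, more than in the real cohort where true values drove
the published sensitivity analysis). Drift knobs
(`intercept_shift`, `slope_multiplier`, fixed intercepts with targets
set to `NA`) allow constructing deliberately miscalibrated cohorts; the
default configuration's miscalibration of the *Motwani mapper* (negative
CITL, slope < 1) arises naturally, because that mapper's development
constants overestimate risk for a cohort whose incidence is 11%.

## Numerical choices, in one place

* Probability clipping before logits: 1e-9, warned.
* Outcome-threshold comparison tolerance: 1e-9 (inclusive reading).
* Generator class-interval safety margin: 1e-7 relative.
* Calibration-curve smoother: local linear regression (loess), span
  0.75, predictions clipped to [0, 1]; decile bins are equal-count with
  ties kept together, merged (with a warning) when distinct values run
  out.
* Intercept solving in the generator: `uniroot` on [−50, 50], tolerance
  1e-10; prevalence targets of exactly 0 or 1 short-circuit to
  degenerate probabilities.
* Separation in recalibration: fitted probabilities within 1e-8 of 0/1.
* Bootstrap replicates with single-class resamples: redrawn, counted,
  reported.

## Problem sizes used by the test and acceptance suites

Marginal- and prevalence-recovery checks run at n = 50,000; slope/CITL
closed-form checks at n = 40,000–100,000; recalibration parameter
recovery at n = 50,000; the slope-CI coverage check uses 30 generator
seeds with 150 bootstrap replicates each; the AUROC-comparison null
calibration uses 200 simulations of n = 150 with 100 replicates; the
end-to-end acceptance computations use the frozen n = 1,684 with 1,000
bootstrap replicates. These sizes give Monte-Carlo error comfortably
inside each asserted tolerance.

## Limitations

The generator's truth model is logistic in the Gupta score by
construction, so recalibration-style repairs look as clean here as the
theory promises; real cohorts can miscalibrate non-logistically.
Prevalence targeting fixes the *expected* event rate — a cohort of 1,684
still carries binomial noise of roughly ±1.5 percentage points in the
labelled C-AKI rate. The Gupta primary model's published spline
coefficients are not reproduced, only the refit-on-reference-cohort
default; users validating against the original model should plug in its
coefficients via the mapper slot. And with 36-odd severe events at the
default size, severe-outcome calibration estimates are as unstable here
as they are in practice — which is faithful, if inconvenient.
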