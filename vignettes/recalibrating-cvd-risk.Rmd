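---
title: "Recalibrating 10-year cardiovascular risk equations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recalibrating 10-year cardiovascular risk equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrecal)
```

## The problem

Clinical 10-year cardiovascular risk equations are developed in one
population and routinely applied in another. Two equations dominate
practice: the ACC/AHA Pooled Cohort Equations (PCE), which predict the
10-year risk of a first hard atherosclerotic cardiovascular disease
(ASCVD) event — non-fatal myocardial infarction, coronary death, fatal or
non-fatal stroke — and the ESC SCORE, which predicts 10-year
*cardiovascular mortality* only. When the background event rate of the
target population differs from the derivation cohorts, a score can rank
subjects well (good discrimination) while systematically over- or
under-predicting absolute risk (poor calibration). `cvrecal` implements
both equations, the intercept-level fix for exactly this failure mode —
*recalibration in the large* — and the evaluation toolkit needed to
demonstrate it: observed event frequencies, incidence rates,
overestimation percentages, decile calibration tables, Harrell's
concordance statistic for censored data, ROC export, and k-fold
cross-validation.

## The risk models

### Pooled Cohort Equations

For each sex (white/other race stratum), the 10-year risk is the survival
form

$$\hat p = 1 - S_0^{\exp(LP - \bar{LP})},$$

where $S_0$ is the baseline 10-year survival, $\bar{LP}$ the population
mean of the linear predictor, and $LP$ a weighted sum of $\ln$-transformed
risk factors: age, total cholesterol (mg/dL), HDL cholesterol (mg/dL),
systolic blood pressure (mmHg, with separate coefficients for treated and
untreated pressure), current smoking, diabetes, and (for women)
$\ln^2$ age and age interactions. Coefficients, $\bar{LP}$ and $S_0$ live
in a versioned JSON constants file (`inst/extdata/
pce_pooled_cohort_white.json`), not in code; the file schema admits
additional race strata but only the white/other stratum ships, matching
the intended European application. Transcription is verified in the test
suite against an independent literal-arithmetic oracle (six hand profiles
to 1e-9) and against the published worked example for the reference
profile (55-year-old, TC 213, HDL 50, SBP 120 untreated, nonsmoker,
nondiabetic: 5.4 % men / 2.1 % women at display precision; the published
worked example prints 5.3 % for men because it rounds the intermediate
"sum of products" to two decimals — full precision gives 5.38 %).

### ESC SCORE (low-risk region)

The SCORE model is cause-specific. For cause $c \in \{\text{CHD},
\text{non-CHD CVD}\}$ with Weibull-type baseline survival

$$S_0(a) = \exp\{-\exp(\alpha_c)\,(a - 20)^{p_c}\},$$

the cause-specific 10-year risk at age $a$ is
$1 - [S_0(a+10)/S_0(a)]^{w_c}$ with
$w_c = \exp\{\beta^c_{chol}(chol - 6) + \beta^c_{sbp}(SBP - 120) +
\beta^c_{smoke}\cdot smoker\}$ (cholesterol in mmol/L, converted from
mg/dL with the fixed constant 38.67). The total risk is the **sum** of
the two cause risks capped at 1 — the published combination rule; the
complement-product alternative `1-(1-r1)(1-r2)` is available behind
`combine = "complement"` but is not the default. The low-risk-region
constants ship in `inst/extdata/esc_score_low_risk.json`.

## Recalibration in the large

The correction factor is the log odds-ratio of the observed event
frequency $O$ (after administrative censoring at 10 years) to the mean
predicted risk $\bar P$:

$$c = \ln\frac{O/(1-O)}{\bar P/(1-\bar P)}.$$

**Scale decision.** The source description says the factor is added "to
the linear predictor", but for the PCE survival form an additive LP shift
is not a log-odds shift, and only the log-odds shift realizes calibration
in the large exactly under homogeneous predictions. The package therefore
applies the correction on the logit of the predicted risk,
$\operatorname{logit}(p') = \operatorname{logit}(p) + c$, by default; an
exponent-shift mode (multiplying $\exp(LP - \bar{LP})$ by $e^c$ inside
the survival formula) is available via `mode = "exponent"` for
sensitivity analysis. Both are strictly monotone in $p$, so Harrell's C
is *exactly* invariant under either recalibration — a property the test
suite asserts at machine precision.

Recalibrated equations serialize to the same JSON schema with an added
`recalibration` block, so a fitted score is shareable and reloadable with
bit-identical predictions.

## Evaluation conventions

* **Observed frequency** defaults to the crude proportion of subjects
  with an event by the horizon. Because mean follow-up in the emulated
  cohorts (8.6 / 9.0 years) is below the 10-year horizon, a
  Kaplan-Meier-adjusted estimator (`method = "km"`, via the survival
  package) is provided, but crude remains the default reported quantity.
* **Overestimation %** is `[(estimated rate / observed rate) - 1] * 100`;
  positive values mean the score overestimates.
* **Decile calibration** uses rank-based sample quantiles (type 2) with
  tied predictions kept in one group; a `ties` attribute flags collapsed
  groups. The per-group `se_pred` column is the binomial Monte-Carlo
  standard error of the observed frequency under the group's mean
  prediction, used by the "within 3 SE" checks.
* **Harrell's C**: a pair is usable iff the smaller observed time belongs
  to an event; equal times are usable only when both subjects have events
  and then contribute 0.5 (no "earlier" subject exists); equal times with
  one censored subject are unusable; prediction ties count 0.5. These tie
  rules are normative for the package and are enforced against a
  brute-force double-loop oracle in the tests. The CI is a seeded
  nonparametric percentile bootstrap over subjects (default B = 1000 when
  requested; metrics-only callers use B = 0). Note that C equals the ROC
  AUC on the event dichotomy only when no event-event pairs exist — AUC
  has no within-case pairs — so the two agree exactly for a single event
  and only approximately otherwise.
* **Cross-validation** stratifies folds on the event indicator (the
  source analysis does not state its folding; stratification guarantees
  an estimable observed frequency in every training split) and is fully
  determined by a required seed. A training split without events (or
  without non-events) refuses with guidance to reduce k; a held-out fold
  without events — possible at extreme k, e.g. leave-one-out — reports NA
  metrics and is skipped by the pooled averages.

## The synthetic-data world

The raw study cohorts are not publicly deposited, so the generator
emulates their published baseline structure and is itself first-class,
tested code:

* Per sex: age from a Normal truncated to [40, 79]; total cholesterol,
  HDL and SBP from log-normal families fitted to the published median and
  IQR ratio (right-skewed, as lipid and pressure data are; a Normal
  alternative per block was considered and rejected as it admits negative
  values at these SDs); treatment, smoking and diabetes as Bernoulli.
  `kora_like_config()` (n = 5,238, follow-up 8.6 +/- 2.0 y) and
  `hnr_like_config()` (n = 4,208, 9.0 +/- 2.1 y) carry the published
  marginals.
* Covariates are sampled independently — the published tables give no
  joint structure, so independence is the honest default.
* Outcomes: the true 10-year risk $p_i$ is either the PCE prediction
  itself (`pce_true`), the PCE odds *divided* by a factor `gamma`
  (`pce_scaled`: gamma is the built-in odds-scale overestimation of the
  score, so gamma = 1.5 produces a cohort in which the original score
  overestimates by construction, the scenario the recalibration is for),
  or a user-specified log-linear hazard (`custom_lp`). Event times are
  exponential within the window with rate $-\ln(1-p_i)/10$, so
  $P(T \le 10) = p_i$ exactly.
* Censoring times are Normal with the location solved (uniroot on the
  closed-form censored mean) so that $E[\min(C, 10)]$ equals the target
  mean follow-up; events still shorten realized follow-up slightly, so
  the realized mean undershoots the target by ~0.3 y in event-rich
  cohorts. `censoring = "none"` follows everyone for the full horizon and
  is what the exact self-consistency and calibration-recovery checks use,
  because with censoring active the crude frequency systematically
  undershoots the mean true risk.
* The share of events flagged as cardiovascular deaths defaults to the
  published fatal/total event ratios (175/383 and 74/271).

A green calibration test on this world establishes that the estimators
and the recalibration algebra are correct; it does **not** establish that
real cohorts satisfy the generator's assumptions (independent covariates,
exponential event times, non-informative Normal censoring, no competing
risks).

## Numerical and degenerate-input choices

* Age window inclusive on both ends (40 <= age <= 79); exclusion
  accounting assigns each removed subject to the *first* failing
  criterion in the fixed order age, prevalent disease, missing endpoint,
  missing risk factor, so the log is deterministic. Unknown
  prevalent-disease flags do not exclude (prevalence cannot be asserted).
* Follow-up exactly at the horizon is left unchanged; an event recorded
  beyond the horizon becomes a censoring at the horizon.
* `compute_correction` and `apply_correction` refuse degenerate inputs
  (frequencies or probabilities at 0 or 1) rather than returning
  infinities.
* Correction round-trips (`+c` then `-c`) are exact to 1e-12; the linear
  predictor uses an explicit row-wise sum rather than BLAS matrix
  multiplication so predictions are bit-identical under row permutation.

## Limitations

Only the white/other PCE stratum and the low-risk SCORE variant are
implemented; no competing-risk structure, no multiple imputation for
missing risk factors, no recalibration beyond the intercept (slope or
full re-estimation are out of scope by design); plot rendering is limited
to data export.
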