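---
title: "Methods: trial-based effectiveness and cost-effectiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based effectiveness and cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcea)
```

## What the package models

`trialcea` implements the full analysis chain of a two-arm (1:1)
randomized controlled trial with repeated psychometric assessments and a
trial-based economic evaluation: a seeded synthetic data generator, a
missing-at-random (MAR) dropout mechanism, multiple imputation with
Rubin's-rules pooling, generalized estimating equations (GEE) for the
adjusted between-group contrasts, a societal cost model, quality-adjusted
life years (QALYs) by the area-under-the-curve method, and a stratified
nonparametric bootstrap producing the incremental cost-effectiveness
ratio (ICER), net monetary benefit (NMB), bias-corrected and accelerated
(BCa) intervals, the cost-effectiveness plane and the cost-effectiveness
acceptability curve (CEAC).

The motivating setting is a supportive-care app for breast-cancer
survivors evaluated against routine care over 6 months, with assessments
at baseline (T0), 3 months (T1) and 6 months (T2) on six instruments —
Body Image Scale (BIS, 0–30), Social Impact Scale (SIS, 24–96),
Pittsburgh Sleep Quality Index (PSQI, 0–21), Multidimensional Scale of
Perceived Social Support (MSPSS, 12–84) and the SF-36 physical/mental
component summaries (0–100) — plus an SF-6D-style health utility in
[0, 1]. All defaults in `trial_config()` describe that study population.

## The synthetic trial generator

Per instrument, a participant's three assessments are multivariate
normal with an exchangeable within-participant correlation `rho`
(default 0.5 — the within-subject correlation of such scales over 3–6
months is typically 0.4–0.6, and no observed value is available; this is
a modelling choice, not an estimate). The control arm follows the
configured drift and the intervention arm additionally receives an
additive effect at T1/T2, so the configured effects are exactly the
estimands of the downstream GEE. Scores are truncated to the instrument
range after the effect is added and integer scales are rounded;
truncation biases marginal means when a configured mean sits near a
boundary (for the defaults only the BIS floor is within ~1.1 SD, and
the bias is shared by both arms). The tests of marginal recovery use
mid-range instruments where truncation is negligible.

Other generator components, each calibrated once to the published arm
summaries:

* **Endocrine therapy** is Bernoulli per arm (52.1% vs 66.7%),
  reproducing the only imbalanced baseline covariate; the analysis
  adjusts for it.
* **Direct medical costs** are lognormal per arm — non-negative and
  right-skewed, as extracted-from-records costs are — with mean equal to
  the published arm mean and SD equal to the published standard error
  times `sqrt(96)`.
* **Inpatient days and clinic visits** are Poisson with arm means
  (1.5, 4.075) and (1.4, 3.931), solved so the expected human-capital
  indirect cost at US$40.79/day matches the published arm means
  (US$144.33 and US$137.31).
* **Health utility** is generated like an instrument, with baseline mean
  0.663 and SD `0.014 * sqrt(96)`, and per-arm shifts matching the
  published adjusted utilities at T1/T2.
* **App usage** (intervention arm only): total 3-month usage minutes and
  login counts are a bivariate lognormal matched to the published median
  and IQR of the whole-program summaries, with a log-scale correlation
  of 0.7 between duration and frequency (heavy users log in more; the
  correlation is a realism choice, set once). Totals are split across the
  three program modules by Dirichlet shares centred on the published
  module means, so module values sum to the totals by construction;
  module-level medians are therefore approximate while whole-program
  medians are calibrated.

The generator does **not** emulate: cross-instrument correlation within
a participant (each scale is drawn independently given arm), item-level
psychometrics, non-monotone intermittent missingness, cost-outcome
correlation, or secular trends. Passing tests therefore demonstrate that
the *analysis machinery* is correct and calibrated under the stated
generative model, not that it would be unbiased under every violation a
real trial could produce.

A single master seed expands into per-stage child seeds
(`child_seed(seed, stage)`), so any stage can be reproduced in
isolation and two runs with the same configuration are byte-identical.

## Missingness

Dropout is monotone and restricted to follow-ups: a participant misses
T1+T2 or T2 only (split 50/50 by default; the published flow diagram
does not give the split). Under MAR the per-participant dropout
probability is logistic in the standardized baseline stigma score
(coefficient 0.6) and arm (0.2), with the intercept solved numerically
so the expected rate equals the target (default 37/192 ≈ 19.3%, the
published attrition). Baseline rows are never masked, and costs/usage
are administrative records that stay complete — consequently costs are
never imputed.

## Multiple imputation

The default engine is per-instrument chained equations with
predictive-mean matching (5 cycles, 5 donors): each follow-up value is
regressed on arm, endocrine therapy, the instrument's baseline value and
the other follow-up, coefficients are drawn from their approximate
Bayesian posterior, and each missing case copies the observed value of
one of its nearest predicted neighbours. PMM keeps scale totals integer
and in range. The sensitivity engine (`method = "mcmc"`) draws from the
joint multivariate normal, which under monotone dropout factorizes into
sequential conditional normals; draws are clipped to the instrument
range. Imputation is per instrument (conditioning on that instrument's
own trajectory), a simplification that forgoes cross-instrument
information.

`m = 20` imputations by default: the published analysis does not state
`m`, and 20 keeps the Monte-Carlo component of pooled estimates below
reporting precision at ~20% missingness. Pooling by Rubin's rules is
applied to GEE coefficients and contrasts (`pool_rubin()`), with
t-inference on Rubin's small-sample degrees of freedom — never to raw
data summaries.

## The effectiveness model

`fit_gee()` models the T1/T2 responses with an identity link:

    y_it = b0 + b1 group_i + b2 t2_t + b3 (group x t2)_it
         + b4 endocrine_i + b5 baseline_i + e_it

solved by estimating equations with an exchangeable working correlation
and a robust (sandwich) covariance; convergence is a maximum coefficient
change below 1e-8 (cap 100 iterations, non-convergence flagged and
fatal only at contrast extraction). The working-correlation moment
estimate is clamped to its admissible range.

*Baseline as covariate.* A repeated-measures description ("group, time
and group × time") and adjustment for "baseline outcomes" are only
jointly consistent when the baseline enters as a covariate and the
responses are the two follow-ups; that parameterization also yields
exactly one adjusted group difference per follow-up, which is what the
contrast table reports. The group contrast at T1 is `b1`, at T2
`b1 + b3`.

*Multiplicity.* The Bonferroni family is `k = 2` — the two follow-up
contrasts per outcome — matching pairwise-comparison adjustment within
an outcome; `k` is an argument for users who prefer to span outcomes.

*Effect sizes.* Cohen's d divides the adjusted contrast by the pooled
unadjusted baseline SD, and the minimal important clinical difference
(MICD) is half the baseline SD (distribution-based). With 96 per arm the
pooled two-arm SD and the whole-sample SD agree to two decimals, so
either reproduces published d values.

## The societal cost model

Fixed program costs are amortized as an **annuity-due**: the one-time
development costs plus the annual therapist fee discounted at 3% per
year with the first payment undiscounted,
`PV = one_time + sum_{t=0..Y-1} annual/(1.03)^t`. This convention
reproduces the published 5-year total (US$36,037.68) to the cent from
cent-rounded inputs, where an ordinary annuity (first payment after one
year) does not. The present value is spread over
`horizon_years x periods_per_year x participants` (5 × 2 × 96), giving
US$37.54 per participant per 6 months; the control arm's share is 0.

Indirect costs follow the human-capital approach:
`(inpatient_days + 0.5 x clinic_visits) x daily_income`, with daily
income `annual_income / 260` working days. 10,606.27/260 = 40.79,
whereas the published text prints 40.80; the source's working-day
convention is unstated and the one-cent gap is documented rather than
hidden. Totals are exact component sums; rounding (half-up, 2 decimals)
is applied only when tables are rendered.

## Utilities and QALYs

The licensed SF-6D tariff cannot be redistributed, so utility mapping is
a registry (`register_utility_mapping()`): plug in the real tariff if
you hold a license. The bundled `"sf6d-surrogate"` is an affine map of
the SF-36 summary means, `clip(-0.0548 + 0.0187 (PCS + MCS)/2, 0.29, 1)`,
with coefficients solved so a cohort at the trial's baseline score
moments has mean utility 0.663 and SE 0.014 at n = 96, and a floor at
the published lower bound of SF-6D value sets. It is monotone in each
component and clearly non-tariff.

QALYs are the trapezoid area under the utility trajectory with times in
years. Note a documented inconsistency in the source material: the
published per-arm 6-month QALY totals (~0.377) are not the trapezoid
area of the published utilities (~0.339); the time-scaling behind the
published totals is unstated, the standard trapezoid is implemented, and
the published totals are not used as calibration targets. The published
*incremental* QALY (0.008) is likewise slightly larger than the
trapezoid increment of the published utilities (0.0054). QALYs are not
discounted within the 6-month horizon. QALYs are analyzed with the same
covariate-adjustment machinery as other outcomes (endocrine therapy and
baseline utility).

## Bootstrap cost-effectiveness evaluation

Participants are resampled with replacement **within arm**, preserving
the 1:1 design; per replicate the incremental cost and QALYs are the arm
coefficients of linear adjustments (cost on endocrine therapy; QALYs on
endocrine therapy and baseline utility). An unadjusted fast path exists
for property tests. With multiple imputations the `B` replications
(default 10,000) are divided evenly across the completed datasets and
concatenated, so the draws mix resampling and imputation uncertainty; a
first-imputation-only analysis is available by passing a single dataset.

BCa intervals use the standard bias correction (fraction of draws below
the point estimate, clamped to `(1/(B+1), B/(B+1))`), jackknife
acceleration computed on the first completed dataset (the acceleration
is a smooth functional and stable across imputations), and normal-score
interpolation between order statistics. Degenerate draw sets return the
point as both endpoints.

Decision outputs: ICER with dominance labels (`epsilon = 1e-9` QALYs
for the indeterminate label), NMB at the threshold, CE-plane quadrant
proportions (boundary draws split equally between adjacent quadrants),
and the CEAC over a US$0–200,000 grid in steps of 500 with the decision
threshold at 3 × GDP per capita = US$37,530/QALY.

## Problem sizes used by the test and simulation studies

The package's simulation studies run at the study's own scale where the
property being checked needs it, and smaller where it does not: the
parameter-recovery study uses 200 replicated trials of 96 per arm with
~20% MAR dropout and m = 5 imputations of the primary stigma outcome;
bootstrap coverage uses 200 cohorts of 96 per arm at B = 1,000;
the BCa implementation is cross-checked against the `boot` package on a
10-observation instance at B = 2,000; correlation and marginal recovery
use n = 5,000 per arm. The acceptance script averages the bootstrap CEA
over 10 replicated trials (m = 10, B = 2,000 each) because single-trial
incremental costs have a standard error near US$1,450 — an honest
reflection of why the published cost difference carries a wide CI.

## Known limitations

* The generator's independence across instruments means multivariate
  summaries (e.g. joint utility-and-stigma behaviour) are not realistic.
* Per-instrument imputation ignores cross-instrument predictors.
* The GEE solver is specific to Gaussian identity-link models with an
  exchangeable (or independence) working correlation — exactly the
  models used here, nothing more general.
* The utility surrogate is calibrated to cohort moments; individual
  utilities are not SF-6D tariff values, so absolute QALY levels carry
  that approximation even though between-arm contrasts are unaffected
  under randomization.
* The cost-effectiveness horizon is the trial's 6 months; no decision
  modelling beyond it.
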