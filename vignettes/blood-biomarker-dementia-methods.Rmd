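---
title: "Methods: blood biomarkers and incident dementia in community cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood biomarkers and incident dementia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admarkers)
```

## The scientific problem

Serum biomarkers of Alzheimer-type pathology (amyloid-β 42/40 ratio,
p-tau181, p-tau217), neurodegeneration (total tau, NfL) and astrocyte
activation (GFAP) can be measured from a single blood draw, making them
candidates for dementia risk assessment outside specialist clinics. Two
questions structure the analysis this package implements for
population-based cohorts of older adults followed over many years:

1. **Association** — how does the hazard of incident all-cause and AD
   dementia vary with baseline marker concentration, allowing for
   non-linearity and confounding?
2. **Prediction** — given a fixed 10-year horizon, how well does each
   marker (or a combination of markers) classify who will develop
   dementia, and at what threshold?

## Association models

Time-to-event is modelled with Cox proportional hazards
(`fit_cox()`, partial likelihood via the `survival` package, Efron tie
handling by default with Breslow available). Follow-up runs from baseline
to dementia diagnosis, death, withdrawal or administrative censoring,
whichever comes first. For the AD outcome, other dementias and deaths are
*censored at their event times* (cause-specific hazards), so the at-risk
person-time is identical to the all-cause analysis and only event labels
differ — an identity the test suite asserts. Competing-risk
cumulative-incidence (Fine–Gray) regression is deliberately out of scope:
the estimand is the cause-specific hazard.

All adjusted models use the same covariate set: age (years), sex,
education (indicator-coded with elementary schooling as the reference —
the coding is a package convention, since ordinal coding would also be
defensible), eight chronic-disease flags (hypertension, ischaemic heart
disease, heart failure, atrial fibrillation, cerebrovascular disease,
chronic kidney disease, anaemia, obesity) and *APOE* ε4 carrier status.
Participants missing a covariate are dropped from models that use it;
participants missing any of the six markers are excluded from the
analytical sample altogether. No multiple imputation is attempted.

**Dose–response curves.** Non-linearity is modelled with a restricted
cubic spline with three knots at the marker's 25th/50th/75th sample
percentiles (`rcs_basis()`): a linear term plus one restricted cubic
term, linear beyond the boundary knots with continuous first and second
derivatives. The hazard-ratio curve is the contrast
`exp(η(x) − η(x_ref))` with a delta-method pointwise interval; the
reference `x_ref` defaults to the first knot (the 25th percentile) —
the choice is arbitrary and exposed as an argument, since it only shifts
the curve, not its shape.

**Quartile models.** Markers are also analysed as sample quartiles
(`quartile_assign()`), reference Q1 — except the amyloid ratio, where
low values are pathological, so Q4 is the reference. The trend test
refits the model with the quartile index (1 at the reference, 4 at the
top-risk quartile) as a single ordinal score and Wald-tests its
coefficient; scoring by quartile medians would be an alternative, but
ordinal scores are the simpler, rank-invariant convention, and the
quartile machinery is then invariant to any monotone transform of the
marker (a property the tests check).

**Diagnostics and sensitivity analyses.** Proportional hazards is
checked per covariate by the score test of zero slope when scaled
Schoenfeld residuals are regressed on (untransformed) survival time
(`schoenfeld_check()`); undefined diagnostics (too few events) are
reported as missing. Sensitivity machinery (`analysis_filters()`):
excluding baseline MMSE < 27, truncating follow-up to 6 years with
relabelling of later events as censoring, subgroup strata (age < 78 /
≥ 78, sex, *APOE* carriers/non-carriers, memory complaints), and
stabilized inverse-probability-of-dropout weights
(`ipw_dropout_weights()`): a logistic retention model on age, sex,
education, chronic-disease count and the six markers; retained
participants are weighted by `P(retained)/P(retained | covariates)`
(stabilized rather than raw weights, for bounded variance at the same
estimand), with fitted probabilities truncated at the 1st/99th
percentiles by default.

## Horizon prediction

**Labelling** (`horizon_labels()`): positive = qualifying event within
10 years; negative = event-free follow-up reaching 10 years.
Participants whose follow-up ends earlier without a qualifying event
have unobserved horizon status. The default *excludes* them (with
recorded reasons), because counting them as negatives deflates
sensitivity and NPV with outcomes nobody observed; the
treat-as-negative convention is available behind a flag
(`censored_as_negative`) since either choice is defensible.

**Cut-point estimation** (`bootstrap_cutpoint()`): within each of B
bootstrap resamples of (marker, label) pairs, every *observed* marker
value is a candidate threshold — midpoints between order statistics are
rejected so that a published cut-off stays a raw biomarker value — and
the candidate maximizing Youden's J is selected; ties in J are resolved
by averaging the tied candidates (deterministic and unbiased between
them). Single-class resamples are redrawn and counted. The arithmetic
mean over resamples is the cut-off; B = 5,000 is the reference setting,
and the full-sample distribution of per-resample cut points is retained
for inspection. Cut-offs are derived on the 80% training split only and
then frozen for the 20% test split (`split_train_test()`, training size
`floor(0.8 n)`); deriving them on the full sample before testing would
leak information, so full-sample derivation is possible only by passing
the whole frame explicitly.

**Classification** (`apply_cutoff()`): a value exactly at the cut-off
is positive ("at or above", "at or below" for the amyloid ratio) — the
boundary rule is stated because it is a convention, not a fact of the
data. Confusion metrics come with percentile-bootstrap intervals
(2,000 replicates by default); AUC is the rank (Mann–Whitney) estimator
with a DeLong interval by default (participant bootstrap optional).
Single-marker AUCs use the *continuous* marker; combination predictors
(`combine_elevated()`) use the ordinal count of elevated markers or
binary at-least-k / exactly-k / pairwise-AND rules over p-tau217, NfL
and GFAP. Both the at-least-k and exactly-k families are provided
because "one, two or three elevated markers" is ambiguous between them.
Two identities hold *exactly* on every report and are asserted at test
time: accuracy = sens·prev + spec·(1 − prev) on the classified set, and
PPV/NPV equal their Bayes reconstructions from sensitivity, specificity
and prevalence.

## The synthetic cohort generator

Real community-cohort data of this kind are access-restricted, so the
package carries a generator (`sim_config()`, `simulate_cohort()`) whose
defaults *are* the study conditions the analysis assumes; they are fixed
once and not tuned per analysis.

- **Biomarkers.** Gaussian copula: latent normal scores with Pearson
  correlation `2·sin(πρ_s/6)` reproduce the target Spearman matrix
  exactly under monotone marginal transforms (nearest-positive-definite
  repair by eigenvalue clipping if a hand-edited target matrix needs
  it). The six published pair targets (0.86, 0.65, 0.62, 0.61, 0.55,
  0.53) are defaults; unpublished pairs are set to modest positive
  values, negative for the amyloid ratio. Marginals are log-normal
  (logit-normal for the bounded ratio) with medians and spreads chosen
  once to be plausible for serum Simoa assays (e.g. NfL median
  ≈ 15 pg/ml, GFAP ≈ 112 pg/ml, ratio ≈ 0.061); the source cohort
  published no marginal distributions, so these are modelling choices,
  not published facts.
- **Covariates.** Margins of a Swedish urban 60+ cohort (age
  72.8 ± 10.6 truncated to 60–101, 61.6% female, education 15/49/35%,
  eight disease prevalences, MMSE 28.6 ± 1.9, 69.3% memory complaints,
  29.2% *APOE* ε4 with ~2% missing genotype). Joint structure between
  covariates, and between covariates and biomarkers, is *not* modelled.
- **Dementia hazard.** Weibull proportional hazards
  `H(t | x) = λ t^k e^{lp}` with shape k = 1.4 (incidence rising with
  time in an ageing cohort). Marker effects act on the latent copula
  score: flat below the marker's 25th percentile, linear above it
  (inverted for the ratio) — the threshold shape seen in spline curves
  from real cohorts. The baseline rate λ is *calibrated by root-finding*
  so that expected events per 100 person-years — Monte-Carlo-integrated
  over the covariate distribution with competing death, dropout and
  censoring, on a fixed internal seed (the calibration is part of the
  model, not of any particular draw) — hits the target 1.82 within 1%.
  Event times by inverse-transform sampling; AD vs other dementia by an
  independent Bernoulli(0.582) at event time — the simplest mechanism
  consistent with a reported subtype fraction, with no subtype-specific
  hazards.
- **Competing death and dropout.** Death is an independent Weibull
  (shape 1.5) depending on age, disease count and sex but, by default,
  not on biomarkers — so cause-specific censoring is informative only
  when a user configures it to be. Withdrawal is a baseline Bernoulli
  flag with logistic dependence on age (younger), education (more
  educated) and disease count (healthier) — the published dropout
  profile — with a uniform withdrawal time; ~6% withdraw.
  Administrative censoring at 16 years. Values below per-marker
  detection limits are *kept raw* by the generator; imputation to 0
  (the not-missing-at-random single-value convention for these assays)
  is an explicit, counted preprocessing step, and the default limits
  leave a sub-percent left tail comparable to the handful of imputed
  measurements reported for the real panel.

**What passing tests do and do not show.** The generator reproduces the
cohort-level quantities it is calibrated to (incidence rates, rank
correlations, subtype fraction, dropout profile) and the qualitative
threshold-shaped dose–response. It does not reproduce covariate–biomarker
confounding (biomarkers are independent of age by construction), joint
disease structure, repeat measurements, or any particular cohort's
quartile boundaries, hazard ratios and cut-offs. Green tests therefore
certify the *machinery* — estimators agreeing with oracles, identities
holding, parameters recovered at known truth — not agreement with any
real cohort's published effect estimates, which are unreachable without
the restricted data.

## Numerical conventions and degenerate inputs

- Percentiles everywhere (quartiles, knots, weight truncation) use
  linear interpolation between order statistics; the convention is fixed
  and stated because it moves knot and quartile placement slightly and
  the source analysis named none.
- Values exactly at a quartile boundary go to the lower quartile
  (deterministic, order-independent); all-tied cut points are an error
  flagged as degenerate, as is standardizing against a zero-variance
  reference or placing knots with fewer than 10 distinct values.
- Incidence-rate intervals are exact Poisson (chi-square inversion) —
  the method behind published bounds is unstated, so second-decimal
  differences from printed intervals are expected.
- Monotone likelihood (complete separation) in a Cox fit is reported as
  an error, not returned as a huge coefficient; single-class inputs to
  cut-point or AUC routines are errors.
- Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; a full `run_all()` writes byte-identical artifacts
  on repeat runs, with independent seeds per randomness source
  (simulation, split, bootstrap, CI) so stages can be re-run in
  isolation.

## Problem sizes in the shipped tests

The test suite exercises the generator at n up to 50,000 (incidence
calibration) and 100,000 copula draws (correlation recovery); Cox
parameter recovery at n = 5,000; bootstrap cut-point recovery of the
analytic equal-variance binormal threshold (midpoint of class means at
prevalence ½) at n = 2,000 with B = 500; IPW bias reduction over 100
replicates of n = 1,500; exhaustive-oracle equivalence on hundreds of
small random instances; and an end-to-end demo pipeline at n = 900 with
B = 100. These sizes give stable Monte-Carlo behaviour at interactive
runtimes; the reference settings for a real analysis remain n ≈ 2,148,
B = 5,000 and 2,000 CI replicates.

## Known limitations

Beyond the generator simplifications above: no external validation
machinery across cohorts (the estimand is internal 80:20 validation); no
time-dependent ROC with censoring weights (the horizon rule is the
stated exclusion convention instead); no frailty or subdistribution
hazards; no multiplicity adjustment across markers (none is conventional
in this analysis family); trend tests and education coding follow the
stated conventions where the field's practice varies.
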