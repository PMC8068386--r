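---
title: "A composite CPET score for PAH screening in connective tissue disease: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A composite CPET score for PAH screening in connective tissue disease: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpetscore)
```

## The clinical problem

Pulmonary arterial hypertension (PAH) is a pre-capillary pulmonary vascular
disease and a leading cause of death in connective tissue disease (CTD),
particularly systemic sclerosis. Because early treatment dominates
prognosis, CTD patients are screened regularly, but the standard screening
pathway is sensitive rather than specific: many screen-positive patients
undergo right heart catheterization (RHC) — an invasive test — needlessly.
Cardiopulmonary exercise testing (CPET) probes the physiology PAH disturbs:
a failing pulmonary circulation limits exercise cardiac output (low peak
VO~2~), wastes ventilation (high VE/VCO~2~ slope) and lowers resting
end-tidal CO~2~ (PetCO~2~).

`cpetscore` implements a three-point composite score over those markers and
the full diagnostic-accuracy machinery around it, together with a
calibrated synthetic cohort generator so the whole pipeline can be
exercised and validated without patient-level data.

## The composite score

With thresholds `score_thresholds()` (defaults 14.1 ml/kg/min, 33.96, and
27.2 mmHg), a patient accrues

* 1 point if peak VO~2~ ≤ 14.1 ml/kg/min,
* 1 point if VE/VCO~2~ slope > 33.96 (strictly),
* 1 point if basal PetCO~2~ ≤ 27.2 mmHg.

The inequality directions, including which are strict at the boundary, are
taken as exact. A patient missing any one input is excluded and tallied —
there is no partial scoring, because a 2-of-2 score is not comparable to a
2-of-3 score. The screening decision dichotomises at the full 3 points
(`value >= 3` for the integer marker).

Thresholds are configuration, not constants: `run_pipeline(...,
use_youden = TRUE)` re-derives all three cutoffs from the data by the
Youden index and rebuilds the score with them, closing the loop between
threshold selection and scoring.

## Accuracy statistics and their methods of record

All accuracy computation flows through a 2×2 table (`two_by_two`). The
methods were chosen to be mutually consistent and are fixed as the
package's methods of record:

* **Sensitivity/specificity CIs** — exact Clopper–Pearson from Beta
  quantiles. Exact intervals (not Wilson or Wald) are the natural choice at
  the tiny case counts this setting produces (8 diseased subjects).
* **Likelihood ratios** — `LR+ = sens/(1−spec)`, `LR− = (1−sens)/spec`,
  with intervals by the log method:
  `se(log LR+) = sqrt(1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn))` and the
  analogue with `fn`, `tn` for LR−. The z-quantile is `qnorm(0.975)` =
  1.959964, not a rounded 1.96; this moves third decimals. A zero cell
  yields a signalled `Inf`/`0` with undefined interval; an optional
  Haldane–Anscombe +0.5 correction is available behind a flag, off by
  default.
* **Predictive values** — Bayes at a stated pre-test prevalence (default
  10%, the assumed PAH rate among screened CTD patients): pre-test odds ×
  LR = post-test odds. Their intervals push the LR interval endpoints
  through the same transform, which keeps every reported quantity a
  function of the same 2×2 and prevalence. At the sample prevalence this
  reproduces the raw `tp/(tp+fp)` and `tn/(tn+fn)` exactly (a tested
  invariant).
* **ROC/AUC** — the empirical curve over all distinct observed cutoffs plus
  sentinel endpoints, so `sens = 1` and `sens = 0` always appear. The AUC
  is the midrank Mann–Whitney probability (ties count ½); its CI uses the
  DeLong placement-value variance. No smoothing, no binormal model, no
  interpolation between the integer score's operating points.
* **Youden selection** — maximises `J = sens + spec − 1` over operating
  points; ties break toward higher specificity (a screening follow-on test
  should spare RHCs), then toward the threshold closest to the pooled
  sample median ("least extreme"), then first-in-order. Equality is judged
  at 1e-12 to keep floating-point noise from flipping ties.

## Cohort-comparison statistics

`kruskal_wallis()`, `pearson_chi2()` and `chi2_trend()` are computed from
their defining formulas (midranks with the tie-correction factor
`1 − Σ(t³−t)/(N³−N)`; expected counts from margins without continuity
correction; the unconditional Cochran–Armitage statistic `T²/Var` with
default scores 0–3). P-values use the chi-squared approximation throughout
— appropriate at these group sizes, and the trend test's type-I error is
verified by simulation to sit near its nominal 5%. The base-R
implementations (`kruskal.test`, `chisq.test`) serve as independent oracles
in the test suite, never as the computation path. Post-hoc pairwise flags
use Mann–Whitney tests with Bonferroni adjustment — a documented stand-in,
since no canonical post-hoc procedure exists for this table structure.

## Breath-by-breath feature derivation

`breath_series` objects carry time, VE, VO~2~ and VCO~2~ channels plus
three protocol markers (rest end, loaded-exercise start, isocapnic
buffering end). Choices:

* **VE/VCO~2~ slope** — OLS of VE (L/min) on VCO~2~ (converted to L/min)
  from one minute after loaded-exercise start to the buffering-end marker;
  the unit conversion makes the slope dimensionless and comparable to the
  33.96 cutoff. At least 3 in-window samples and nonzero VCO~2~ variance
  are required.
* **First ventilatory threshold (V-slope)** — "VCO~2~ rising faster than
  VO~2~" is operationalised as a two-segment piecewise-linear least-squares
  fit of VCO~2~ on VO~2~ over the exercise samples, breakpoint minimising
  total RSS subject to `slope2 > slope1` with ≥ 3 points per segment. A
  perfectly linear relationship has no admissible breakpoint and returns a
  *not-detected* signal rather than an error. The slope constraint uses a
  relative tolerance of 1e-8 so numerically equal slopes never qualify.
* **Peak VO~2~** — maximum of means over non-overlapping 10-s time bins,
  the conventional reporting average; bin averaging can shave up to one
  inter-sample increment off a ramp's instantaneous maximum.
* **Maximal effort** — RER strictly above 1.10. RER is computed as
  VCO~2~/VO~2~, the physiologic convention.
* Detection of the isocapnic-buffering end is deliberately out of scope;
  the marker is supplied with the series.

## The synthetic cohort generator

No public patient-level data exist for this setting, so the generator
emulates the published group structure: 112 CTD, 8 CTD-PAH and 11
other-etiology PH patients (131 total), each variable summarised by a
median and IQR, and per-group male/female counts 11/101, 1/7 and 4/7.
Those published summaries *are* the generator's defaults
(`default_group_specs()`).

* **Marginal family** — log-normal for every physiologic variable: the
  minimal two-parameter family on positive support that carries skew.
  `mu = log(median)` matches the median exactly; `sigma` is the
  least-squares solution of the two quartile equations,
  `(log q3 − log q1)/(2 qnorm(0.75))`. A consequence worth knowing: the
  family is log-symmetric about the median, so strongly asymmetric
  published IQRs (e.g. a VT1 summary of 64 (24–73)) are honoured in spread
  but not skew — the fitted quartiles, not the raw published ones, are
  what the generator reproduces, and calibration tests are stated against
  them.
* **Sampling** — independent margins use stratified
  (Latin-hypercube-style) inversion: one uniform per equal-probability
  stratum, permuted. Sample quantiles then converge to the calibration
  targets at O(1/n), which is the point of a generator whose job is to
  match published medians and IQRs. When a Spearman rank-correlation
  matrix is supplied, the affected variables are coupled through a
  Gaussian copula (`r = 2 sin(πρ/6)` on the latent scale) with plain
  Monte-Carlo normals, since mixing would destroy per-margin
  stratification. The default is independence — no correlations were
  published.
* **Missingness** — an optional per-field missingness rate (default 0) on
  the CPET fields exercises the missing-data paths.

What passing tests on synthetic cohorts do *not* show: the generator has
independent margins by default, log-normal tails, no measurement error
model and no treatment effects, so single-marker AUCs on synthetic data are
qualitative only — they need the real joint distribution, which is not
publicly available. Everything derived from the published score-by-status
contingency, by contrast, is exact.

## Problem sizes used in validation

The test suite validates oracle equivalences (AUC vs exhaustive pair
counting, Youden vs exhaustive scan) on randomly generated inputs of up to
50 subjects; Clopper–Pearson coverage by 10,000 binomial replicates at
p = 0.1, n = 120; the trend test's type-I error by a 5,000-replicate null
with four categories of 100 subjects at event rate 0.1; and generator
calibration at 5,000 subjects per group. These sizes give the simulations
stable estimates while keeping the full suite fast.

## Known limitations

* The composite score's headline accuracy rests on 8 PAH cases; the exact
  intervals are wide and honest about that.
* Predictive values are prevalence assumptions, not cohort frequencies;
  change `prevalence` in `pipeline_config()` for other settings.
* The generator cannot represent quartile asymmetry beyond the log
  transform, nor inter-variable dependence unless supplied.
* The V-slope breakpoint fit assumes a single threshold; data with a
  flat-then-steep-then-flat pattern (e.g. plateauing effort) can place the
  breakpoint at the wrong knee.
* No comparison-of-AUCs test, bootstrap intervals, or integration with
  other screening algorithms.
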