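---
title: "Methods: adherence trajectories from pharmacy claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adherence trajectories from pharmacy claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`adheretraj` implements a complete longitudinal medication-adherence
analysis for administrative pharmacy-claims data, of the kind used to study
biologic therapy in inflammatory bowel disease (IBD): new-user cohort
construction, monthly proportion-of-days-covered (PDC) series, data-driven
trajectory clustering, a multinomial model of trajectory determinants, and
follow-up switching/drug-use descriptives. Because patient-level claims
cannot usually be shared, the package also contains a synthetic claims
generator with known latent trajectory classes, so the whole pipeline is
testable end to end. This vignette documents the methods, the defaults, and
the design decisions.

## The analysis pipeline

### New-user cohort

`identify_new_users()` applies a fixed-order inclusion cascade to raw
registry/dispensing/event tables:

1. at least one dispensing of an eligible biologic (adalimumab `L04AB04`,
   infliximab `L04AB02`, golimumab `L04AB06`, vedolizumab `L04AA33`,
   ustekinumab `L04AC05`) inside the study window (default
   2010-01-01..2019-12-31); the first such dispensing defines the index
   date and index drug;
2. ustekinumab indexes only on/after 2018-09-01 (its IBD market entry);
3. at least 365 days of registry observation before the index date;
4. no eligible biologic dispensing in the 365 days before the index date
   (new-user washout — the washout may look before the study window
   opens);
5. registry coverage through the whole follow-up (36 months by default,
   60 for the five-year analysis);
6. an IBD indication (Crohn's disease or ulcerative colitis), determined
   from diagnosis and co-payment-exemption codes on or before the index
   date, most recent code winning and ties resolving to CD.

Each step's entering/excluded/retained counts form the attrition table.
Covariate flags follow explicit window conventions: comorbidities use all
history *strictly before* the index date; drug-use flags use the half-open
window `[index - 365, index)`; events dated exactly on the index date count
as neither. These conventions are arbitrary at the margins but make every
boundary testable.

### Monthly PDC

Each dispensing of *q* DDDs (defined daily doses) covers `round(q)` whole
days from its dispensing date, at one DDD per day. Coverage intervals are
unioned per patient, so days covered by overlapping dispensings (e.g.
loading doses) count once; coverage by *any* eligible biologic counts, so
switching does not interrupt adherence. Follow-up is split into
index-anchored calendar months (day-of-month preserved, clamped at
month-end; 28–31 days each), giving every patient exactly `T` windows;
monthly PDC is covered days divided by window length. Months are anchored
at the index date rather than the calendar year so that all patients have
the same number of windows from treatment initiation; the convention is
switchable in principle but fixed here.

There is no stockpiling carry-forward and no grace period: early refills'
overlapping days are lost to the union, which is what "counted only once"
means operationally.

### Trajectory clustering

`fit_trajectories()` implements the three-stage nonparametric procedure:

1. **24 change measures** (`compute_measures()`): range, mean, SD and
   coefficient of variation of the series; last-minus-first change and its
   normalizations; OLS slope and R²; first-difference statistics
   (max, SD, mean absolute, max absolute, and their normalizations);
   second-difference statistics (mean, mean absolute, max absolute, and
   their normalizations). Ratio measures whose denominator is exactly zero
   for a subject substitute the smallest nonzero absolute value of that
   denominator in the cohort (zero when the denominator is zero for
   everyone) — this keeps the matrix finite without dropping subjects.
   Series must have at least three values.
2. **Measure selection** (`select_measures()`): drop zero-variance
   measures; among pairs with |r| ≥ 0.95 keep the lower-indexed member;
   PCA on the correlation matrix; retain components by a sampling-guarded
   Kaiser rule; varimax-rotate; select per component the measure with the
   largest absolute loading, deduplicated. The guard replaces the raw
   "eigenvalue > 1" threshold by the null upper edge `(1 + sqrt(p/n))²`
   (Horn's parallel analysis in its asymptotic Marchenko–Pastur form).
   The reason is a real failure mode of the raw rule: any measure that is
   essentially uncorrelated with the rest — in this measure set, the
   slope-ratio and mean-second-difference statistics on near-flat series —
   receives its own principal component whose eigenvalue fluctuates around
   exactly 1. Raw Kaiser therefore admits such noise components roughly
   half the time, and after standardization a selected noise measure gets
   the same weight in the cluster distance as a real one, degrading both
   the partition and the validity-index vote. The guarded threshold is
   deterministic and leaves genuinely shared components untouched.
3. **k-means with a majority vote** (`choose_k()`, `cluster_kmeans()`):
   for each candidate k (default 2–10), `stats::kmeans` with 50 random
   restarts from a fixed seed; ten cluster-validity indices
   (Calinski–Harabasz, mean silhouette, Davies–Bouldin, Dunn, C-index,
   McClain–Rao, Ball–Hall, Xie–Beni, Hartigan, PBM) each vote their
   optimal k; the modal vote wins, ties resolving to the smaller k. A
   `forced_k` override implements a clinical-plausibility judgement while
   still reporting the tally. Pairwise-distance indices are computed on a
   seeded subsample of at most 2000 rows to bound the quadratic cost; the
   Hartigan rule uses its original form (smallest k with H(k) ≤ 10, else
   the largest candidate — with thousands of subjects it effectively
   always votes the maximum, a known large-n degeneracy that we keep as
   one vote of ten rather than reinventing the index).

Clusters are ordered by descending mean PDC and, when k = 3, labelled
high/medium/low.

### Determinants model

`fit_multinomial()` is a Newton–Raphson maximum-likelihood multinomial
logit against the high-adherence reference outcome, with Wald standard
errors from the inverse observed information. Convergence requires a
gradient max-norm below 1e-8 (or a relative log-likelihood change below
1e-10), tight enough that two-outcome fits agree with `glm()` binary
logistic regression to better than 1e-6; `nnet::multinom` serves as an
independent three-outcome cross-check in the test suite. Aliased columns
and empty factor levels are dropped with warnings; terms with
|coefficient| > 15 or SE > 100 are flagged as possibly separated.
`or_table()` reports `exp(coef)` with 1.96-SE Wald intervals and no
multiplicity adjustment, matching standard pharmacoepidemiologic
reporting. `stepwise_aic()` is a bidirectional stepwise search from the
intercept-only model, moving whole categorical blocks, with AIC ties
preferring the smaller model and then alphabetical order; the visited path
is returned. Age enters as bands (<18, 18–44 reference, 45–64, 65–79,
≥80), with the two oldest bands sharing one generating coefficient in the
simulator so a collapsed "older" contrast is recoverable.

### Follow-up descriptives

`detect_switch()` finds the first dispensing strictly after the index date
of a different active substance, or the same substance with a different
product type (originator vs biosimilar); same-day mixed dispensings at the
index date are flagged for review rather than counted.
`followup_drug_use()` counts each patient once per drug class (ATC-prefix
code lists) within `(index, index + T months]` and reports per-cluster
percentages and median/IQR days to first switch (linear-interpolation
quantiles, `type = 7`).

## The synthetic claims generator

`simulate_population()` emulates an administrative claims database with a
known truth, for validation. Its defaults are the study conditions the
package targets; they were chosen once and are all overridable.

**Classes and covariates.** Baseline covariates are drawn independently
from configurable marginals (male 55.5%; age bands 6.1/49.8/36.0/7.8/0.3%;
index drug 47.3/4.9/41.2/0.4/6.1% for
adalimumab/golimumab/infliximab/ustekinumab/vedolizumab; biosimilar 22.4%;
CD 58.2%; twelve regions). The latent trajectory class is then drawn from
a multinomial logit on those covariates whose coefficients encode the
reference odds ratios (female 1.52 and older 1.44 for low-vs-high
adherence; biosimilar 0.47; golimumab 0.46, infliximab 0.78, ustekinumab
0.10, vedolizumab 0.30; CD 1.35 for medium-vs-high), and whose intercepts
are calibrated by Newton root-finding (`calibrate_intercepts()`) so the
marginal class shares equal the 19/46/35% mixture to 1e-4. Drawing
covariates first and class second matches the estimand of the determinants
model.

**Target curves.** The three class archetypes are: constant 0.95 (high);
linear decline from 0.95 to a 0.70 plateau at month 9 (medium); linear
decline from 0.90 to 0.20 at month T (low). The plateau, endpoint and high
level follow the reported trajectory descriptions; the start levels are
calibration choices. Subjects deviate from their archetype through a
logit-scale level shift (SD 0.18), a linear logit drift (SD 0.50 by the
end of follow-up), and stationary AR(1) refill noise parameterized by the
magnitude of month-to-month supply changes (`d_noise`, logit SD 0.18/1.0/
0.30 for high/medium/low) and its persistence (0.65/0.15/0.50), with
lognormal subject-level magnitude (SD 0.10) and persistence jitter (SD
0.08). The volatility profile is deliberately hump-shaped: a ~70% plateau
maintained under continuing biologic use is produced by frequent
irregular gaps, so the medium class is the most erratic month to month,
while high adherers refill steadily and low adherers fade with moderate
irregularity. This gradient is what makes the fluctuation-type change
measures genuinely informative, as they are in observed claims data; with
three classes the between-class structure has rank two, so the level/trend
contrast and the fluctuation contrast are the two crisp factors the
selection stage can recover.

**Dispensings.** In `exact` mode one dispensing is placed at each monthly
window start, sized so the realized monthly PDC equals the subject's
target up to whole-day rounding. Quantities use unbiased randomized
rounding (floor plus a Bernoulli fractional day) rather than deterministic
rounding: deterministic rounding imprints an identical quantization
pattern on every subject sharing an index-date month-length sequence,
creating artifactual micro-clusters; randomized rounding stays within one
day per window and removes the lattice. In `noisy` mode fixed pack sizes
(28 DDDs subcutaneous, 56 intravenous) are dispensed at refill intervals
stretched by the inverse of the local target PDC and jittered by a few
days. Switchers (per-class probabilities 32.6/45.5/25.8%) change substance
(or product type, 30% of switches) at a uniform time in follow-up.

**Distractors.** A configurable fraction of subjects (2% each by default)
violate exactly one cohort rule — washout, look-back, follow-up coverage,
or missing IBD indication — and are labelled as such, so the attrition
cascade can be checked violator by violator. Washout violators have an
early-window index with a pre-window dispensing inside the washout
look-back, the only construction compatible with "index = first eligible
dispensing in the study window".

**What the generator does not emulate.** Regional care heterogeneity,
mortality, seasonal or calendar-time effects, dose titration, pack-size
heterogeneity beyond two sizes, correlated comorbidity structure, and
informative censoring. Passing recovery tests on this generator shows the
pipeline implements its stated contracts and can recover a known
three-class structure of realistic shape and noise; it does not show that
real IBD cohorts contain exactly three classes.

## Numerical and scale choices

- All randomness flows from one seed, fanned to per-stage substreams by a
  stable string hash, so any stage re-run in isolation reproduces its
  in-pipeline stream; two runs with the same configuration are
  byte-identical (verified on output digests).
- Validation problem sizes: the test suite exercises the full pipeline at
  n = 2,000 and n = 10,000 subjects and determinant recovery on ten
  cohorts of n = 20,000; measure-level oracles use 1,000 random series.
- Half-up rounding for DDD-to-days conversion; `quantile(type = 7)` for
  switch-timing summaries; Wald (not profile) intervals; k-means with 50
  restarts and up to 200 iterations.
- Degenerate inputs fail loudly: duplicate registry rows, non-positive
  dispensed quantities, series shorter than three months, non-finite
  measure matrices, fewer than two distinct clustering rows, and
  non-converged fits all raise errors rather than propagating.

## Limitations

- PDC measures coverage, not ingestion or dose intensity; one DDD per day
  is an approximation that is coarse for weight-based intravenous dosing.
- The index-anchored month convention differs from calendar months; both
  are defensible and results can differ at the margins.
- Stepwise AIC inherits the known instability of stepwise procedures; the
  default analysis fits the full covariate set and stepwise selection is
  opt-in.
- The majority rule across ten validity indices includes indices with
  known large-n biases (Hartigan, McClain–Rao, C-index); they are retained
  for fidelity to the battery-voting approach, and the modal vote with
  small-k tie-breaking absorbs them.
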