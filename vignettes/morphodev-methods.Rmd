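---
title: "MorphoDev: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MorphoDev: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models MorphoDev implements,
the conventions it fixes where the field leaves room, and the
numerical choices a maintainer should know about. The package analyses
cross-sectional pediatric morphometry tables: per-child regional
volumes (mm³) and cortical thickness (mm) on the Desikan–Killiany
parcellation, with subject metadata (age in months, sex, eTIV in mm³).

## The cohort container

`MorphoCohort` extends `SummarizedExperiment`: rows are
(region, hemisphere, measure) features, columns are subjects, the
single `value` assay holds native-unit measurements with `NA` for
missing entries. The validity method enforces positive ages and eTIV,
non-negative measurements, unique keys, registry-known regions, and
thickness restricted to cortical regions. The packaged registry
(`inst/extdata/dk_registry.tsv`) carries the 34 bilateral
Desikan–Killiany cortical parcels plus common subcortical structures;
11 paired regions form the fronto-limbic analysis set (8 cortical — the
thickness multiple-testing family — plus thalamus, amygdala,
hippocampus).

Subjects missing one hemisphere of a (region, measure) pair are
excluded per-region from asymmetry computation but retained for
unilateral trajectory fits; this maximizes usable data without
imputation.

## Normalization

* Relative volume = volume / eTIV × 1000 (dimensionless, per-mille of
  intracranial volume).
* Relative thickness = thickness / subject's hemisphere mean cortical
  thickness.

**Hemisphere mean thickness.** A whole-hemisphere mean thickness is,
by FreeSurfer's own convention, surface-area weighted. Per-subject
areas are not part of this data model, so the default weights are the
registry's typical regional surface areas (fixed, hemispherically
symmetric); an unweighted mean is available
(`hemisphereMeanThickness(, weighting = "unweighted")`). With
symmetric weights the choice has no effect on asymmetry inference and
only a mild effect on relative-thickness trajectories.

**AI input scale.** AI = (L − R)/(L + R) is computed on raw values by
default: for volumes the eTIV denominator cancels algebraically (the
test suite asserts raw-vs-relative equality to 1e-12), and for
thickness the two hemisphere-mean denominators differ only slightly.
`computeAsymmetry(, scale = "relative")` selects normalized inputs.

## Trajectory model

Each (region, hemisphere, measure) series is fitted with mgcv as

`value ~ sex + s(age, bs = "cr", k = 6)`, REML smoothing-parameter
selection. Defaults: cubic regression spline basis, basis dimension
k = 6 (maximum edf 5 — appropriate for cohorts of a few dozen subjects
over a ~5-year span; larger k is available via `smoothSpec()`), sex
coded female-reference so `sex_coefficient` is the male offset.
Reported per fit: the smooth's effective degrees of freedom (trace of
the influence matrix attributable to s(age); 1 = linear), the
approximate F and p of the smooth, BIC of the candidates
{intercept + sex, linear + sex, smooth + sex} (the smooth's parameter
count is its edf, via the gam log-likelihood), the BIC-selected model
with exact ties broken toward the simpler candidate (intercept <
linear < smooth), and a sex-averaged fitted curve on an integer-month
grid with pointwise ±2·SE intervals.

**Degenerate inputs.** When the linear model already interpolates the
data (relative residual sum of squares below 1e-10 — e.g. noiseless
simulated input), REML/GCV smoothing-parameter selection is ill-posed
and mgcv's optimizer fails informatively while reporting an arbitrary
edf. `fitTrajectory` detects this and returns the infinite-penalty
limit instead: the linear fit, edf = 1. BIC is then evaluated with a
variance floor under which the simplest interpolating candidate wins —
the correct σ² → 0 limit of BIC. Constant data likewise select the
intercept model. p-values are clamped to (0, 1].

**Families for FDR.** q-values are Benjamini–Hochberg within
(measure, hemisphere) families — 11 volume or 8 thickness regions per
hemisphere, hemispheres fitted and corrected separately since left and
right trajectories are reported separately. Pooling both hemispheres
into one family (16/22 tests) is available via
`fitAllRegions(, fdrFamily = "pooled")`.

**Demographics.** Group comparisons of eTIV/age use one-way ANOVA plus
Fisher's LSD (unadjusted pairwise t-tests on the pooled within-group
variance, `pairwise.t.test(pool.sd = TRUE, p.adjust.method = "none")`).
Age groups default to `clamp(floor(age/12), 1, 5)`; the binning is a
config-level choice, overridable by supplying `age_group` directly.
An ordering string like `"1 < 2 < 3 < 4 < 5"` is emitted only when all
adjacent LSD comparisons are significant and means increase in order.

## Sliding-window asymmetry emergence

Windows are 12 months wide and advance by a 1-month stride from the
youngest age while `start + width ≤ max(age) + stride`; membership is
the half-open interval [start, start + width). Dense sliding (stride
1) is the default because it localizes the onset to the stride
resolution; non-overlapping windows are `stride = width`. An
`integer-inclusive` convention floors starts to whole months and
reports windows as inclusive integer ranges, putting midpoints on half
months (a 12-month window starting at 14 has midpoint 19.5) — the
midpoint grid that per-month tabulations of such analyses display.
Strides wider than the window leave coverage gaps and warn.

Each (region, window) set of AI values is tested against zero with the
Wilcoxon signed-rank test; BH correction runs across regions within
each (window, measure) — keeping the 8/11-region family sizes per
window. Correcting across windows within a region instead is available
(`fdrFamily = "per-region"`) but flagged experimental: overlapping
windows make those p-values strongly dependent. A region's initial
point is the midpoint of the earliest window with q < α; the direction
is the sign of that window's mean AI. Significance is strict
(`q < alpha`), matching the usual "FDR-corrected p < 0.05" reporting
convention; note q can equal 1 exactly (a capped two-sided p), so even
`alpha = 1` does not force every window significant.

**Wilcoxon conventions.** Zeros are dropped (classic convention, not
Pratt); tied absolute values get midranks. The null is exact where
feasible: the signed-rank distribution for tie-free samples up to
n = 25, and full enumeration of all 2ⁿ sign assignments of the
midranks when ties are present and n ≤ 14 — so that, e.g., a window of
10 identical AI values still attains its exact two-sided p of 2/2¹⁰.
Beyond those sizes a normal approximation with tie and continuity
corrections is used. Windows with fewer than 5 values are emitted but
untestable; with exactly 5, p is reported but two-sided exact
significance at α = 0.05 is unattainable (minimum p = 1/16).

## The synthetic cohort generator

`simulateCohort` emulates the *value-level* structure of a preschool
morphometry study: 57 subjects by default, ages 14–71 months (uniform,
or stratified 7/15/14/11/10 per year-group), 41/57 male fraction,
eTIV = 1.05·10⁶ + 5000·age + N(0, 7·10⁴) mm³. Each region's bilateral
mean follows a constant/linear/logarithmic/quadratic form in age;
hemispheres are L = m(age)(1 + a(age)), R = m(age)(1 − a(age)) with
a(age) = δ·smoothstep((age − T)/width), so the noise-free AI equals
a(age) exactly; Gaussian noise (log-normal optional) is added per
hemisphere. The smoothstep ramp is a deliberate, recorded choice — any
sigmoid would do; ground truth (spec table, seed, linearity flags) is
attached to the cohort's metadata for recovery scoring.

Default trajectory and lateralization parameters are chosen for
testability at realistic orders of magnitude (volume AI effects
0.05–0.06, thickness 0.025–0.03, onsets spread over 14–35 months,
residual SDs of a few percent), not as biological claims. What the
generator does **not** emulate: site/scanner effects, motion-related
bias, spatially correlated noise across regions, heteroscedasticity
with age, and longitudinal repeat scans — so passing recovery tests
demonstrates the estimators work under their stated model, not that
real pediatric data meet that model.

## Quality control

The population-level QC is a z-score screen: each measurement is
z-scored within its (region, hemisphere, measure) cohort cell and
flagged beyond a threshold (default |z| > 3). Flags are advisory;
`qcAction = "exclude"` (or `applyQcExclusions`) removes them before
analysis. Both modes exist because outlier handling policies differ
across studies. This is a deliberately simple, transparent stand-in
for heavier imaging-QC tooling and operates on extracted values only.

## Validation problem sizes

The test-suite and `scripts/acceptance.R` validate at sizes chosen to
make Monte-Carlo error small while remaining quick on one CPU: 10⁴
random pairs for AI algebra; 500 random vectors (n ≤ 12) against full
sign-pattern enumeration; all 720 permutations of random 6-vectors for
BH; 200 null replicates for the GAM smooth-term size; 100 synthetic
cohorts per planted onset T ∈ {24, 36, 48} months at AI effect 0.15
for emergence recovery (expected recovery: median onset error within
one window width, direction accuracy of significant window calls well
above 95%); and two full pipeline runs compared byte-for-byte for
determinism.

## Known limitations

* Cross-sectional only; no repeated-measures or longitudinal models,
  and no covariates beyond sex.
* edf, F and p for the smooth term are mgcv's approximate quantities;
  with n ≈ 57 and k = 6 they are well-behaved but remain approximations.
* The emergence detector's initial point inherits the window
  conventions; onsets near the age-range boundaries are localized less
  sharply because early/late windows are smaller.
* Reading FreeSurfer stats files covers the aseg/aparc table dialect
  (comment headers, `# ColHeaders`, whitespace rows), not every
  FreeSurfer output variant.
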