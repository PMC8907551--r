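---
title: "Assessing mechanosensitive blood biomarkers: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing mechanosensitive blood biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechmarker)
```

## The scientific question and the two-stage framework

Articular cartilage is avascular; whether walking-scale mechanical load
leaves a measurable trace in blood is the core question behind
"mechanosensitive" serum markers. The experimental design this package
serves is a within-subject crossover: each participant performs a
30-minute treadmill walking bout on three separate days at 80, 100 and
120% body weight, with serum drawn at two pre-test timepoints (t-1, t0)
and three post-test timepoints (t1–t3, up to an hour after the bout).

Two questions are asked in order, each split into a population-average and
an inter-individual part:

* **Criterion I** — does the marker respond to the stress test at all?
  (Ia: non-zero average response; Ib: between-subject variation in
  response.)
* **Criterion II** — for combinations passing criterion I, does the
  response depend on the load magnitude? (IIa: non-zero average slope over
  load levels; IIb: between-subject variation in slope.)

A marker passing criterion II at any selected timepoint is declared
suitable for dose-response work. The gate is deliberately an OR over the
mean and SD branches: a marker responding strongly but heterogeneously
(only σ significant) is as interesting physiologically as one with a
uniform average shift.

## Change scales

Raw concentrations differ by orders of magnitude across markers and
subjects, so the analysis runs on change-from-baseline values against the
same-day t0 sample.

The **absolute** scale divides by the marker's pooled baseline median m
(all subjects, all load days), so the unit is "percent of a typical
baseline level" and markers are comparable. For markers whose raw values
span decades within subjects (ADAMTS-4 in the default configuration), a
log10(1+x) transform precedes the absolute change; otherwise a single
volatile subject dominates m-normalized changes.

The **relative** scale is percent change from baseline with a shifted
denominator, (y_t − y_0)/(y_0 + c) × 100. Plain percent change explodes
when y_0 approaches the detection limit; the shift constant c is the
smallest value capping the maximal relative change at t1/t2 at 75%
(closed form in `select_shift_constant()`). Choices made where the rule is
underdetermined: the cap binds *positive* changes (the responses of
interest are increases); c is selected per marker, pooled over subjects
and loads, so within a marker all subjects share a denominator shift; and
t3 is left out of the cap so late-timepoint behaviour cannot inflate the
shift used at the primary timepoints. The selected constants are exported
with the results for audit.

`baseline_median()` uses the conventional midpoint rule for even counts,
and duplicate ELISA measurements are averaged (`average_duplicates()`)
before any transform; assay precision is summarized per marker as the mean
± SD of duplicate-level CVs, each CV being the two-point sample SD
|x1 − x2|/√2 over the pair mean. CVs are computed on the raw concentration
scale. Pre-test t-1 samples are carried through preprocessing but never
enter change computation; they exist to describe resting-level stability.

## The response model and its inference

With loads coded l ∈ {−1, 0, +1} (centering 100% body weight at 0), the
change value of subject i at load l and a fixed timepoint is

δ_il = α_i + β_i·l + ε_il,

with (α_i, β_i) bivariate normal — means μ_α, μ_β, SDs σ_α, σ_β,
correlation ρ — and i.i.d. normal residuals. α_i is the subject's response
at normal body weight; β_i the change in response per load level. An
average slope of zero is equivalent to no trend in the load-level mean
responses, which is why IIa doubles as the population-level dose-response
test.

Fitting is restricted maximum likelihood. The implementation profiles the
residual variance out of the REML criterion and optimizes the relative
covariance factor on a Cholesky scale (lower-triangular factor, bounded
diagonal), the same parameterization lme4 uses; the test suite verifies
agreement with lme4 to machine precision on full and reduced models. Up to
five jittered restarts guard against ridge-like criteria; the convergence
tolerance is 1e-8 on the criterion.

Numerical edge cases are handled explicitly rather than left to the
optimizer:

* SD estimates below 1e-8 are reported as exact zeros with a boundary
  flag, and the random-effect correlation is undefined (NA) when either SD
  is zero.
* Data in which every subject's points are exactly collinear make the REML
  criterion diverge (zero residual variance). This is detected up front by
  per-subject OLS; the fit degenerates gracefully to the exact
  decomposition (per-subject coefficients, their sample moments) with
  boundary flags instead of raising an error.

**Means** are tested by two-sided Wald tests with a normal reference. The
normal (rather than t) reference is a deliberate choice: the symmetric
intervals it produces match the convention of the summary tables this
layout follows, and at n = 24 subjects the difference is small (the null
calibration test keeps the empirical size inside [3%, 7%]).

**SDs** lie on the boundary of the parameter space under their nulls, so
the usual χ²(1) LRT is wrong. Removing one correlated random effect drops
its variance *and* its covariance with the retained effect; the reference
used is the 50:50 mixture of χ²(1) and χ²(2) (`pchisq_mix()`), the
boundary result for exactly this nesting. When the model holds a single
random effect, the reference is the 50:50 mixture of χ²(0) and χ²(1). The
REML criteria of full and reduced models are comparable because the fixed
effects are identical in both.

**SD confidence intervals** invert the same mixture LRT along the profile
likelihood: one SD is fixed, the other SD, the correlation and the
residual SD are re-optimized, and the interval collects all values within
the mixture critical value of the maximum. Lower bounds clip at zero;
upper bounds are +∞ when the profile never drops below the threshold —
the "0.0 [0.0; ∞]" pattern typical for markers without detectable
heterogeneity. Tying the interval to the same mixture as the test keeps
the two coherent: the interval excludes zero exactly when the test
rejects. A consequence worth knowing: for interior values the mixture
threshold (≈5.14) is stricter than the χ²(1) threshold (3.84), so the
intervals are somewhat conservative and their coverage runs slightly
above the nominal 95%.

No multiplicity adjustment is applied anywhere — every test runs at the
per-test 5% level. This matches the framework's screening character (the
gate is meant to be permissive; downstream studies confirm), but users
scanning many markers should keep the implied family-wise error in mind.

## Criteria gating

`apply_criterion_one()` thresholds the response p-values, and
`apply_criterion_two()` the slope p-values of the same REML fits — the
four quantities come from one model per marker × timepoint, not separate
fits. Gating defaults to the relative-change scale; the absolute-scale
fits are reported alongside as a sensitivity analysis.

Overrides are explicit configuration, never automatic: a combination can
be removed (not added) with a recorded reason. The shipped reference
tables illustrate the intended use — a marker with a significant but
*negative* mean response at a single timepoint, sign-inconsistent with its
other timepoints, is a textbook spurious finding;
`flag_override_candidates()` detects the pattern and proposes, but a human
decides. On the shipped reference slope table the mechanical rule marks
six markers suitable, one via a significant slope-SD alone; a published
prose summary of the same numbers lists five. The package reports the
mechanical verdicts and leaves such editorial judgments to the analyst,
which is why both the verdict table and the per-combination decisions are
returned.

## Correlation analyses

Cross-marker association of *changes* uses the crossover structure: the
Spearman correlation is computed within each load level (midranks for
ties) and averaged over the three levels, removing the load effect before
correlating. Inference bootstraps *subjects* (keeping each subject's full
load profile intact, respecting within-subject dependence; 2000 replicates
by default), then applies a normal approximation on the Fisher-z scale.
The p-value comes from the z-scale normal approximation rather than
percentile inversion, matching the transform-based construction of the
CI. Association of *dose-response slopes* reduces each subject to the OLS
slope of δ on l — with complete loads exactly (δ(+1) − δ(−1))/2 — and uses
the plain Spearman test across subjects.

## The synthetic-data generator

`simulate_change_values()` draws directly from the response model;
`simulate_concentration_panel()` emulates the full study layout so every
pipeline stage is testable without external data: per-subject lognormal
baselines (median and geometric CV per marker), the change-scale response
injected multiplicatively at post-test timepoints relative to the same-day
baseline (so the relative-change transform recovers the injected δ
structure exactly when assay noise is off), duplicate measurements with
lognormal multiplicative noise at the marker's intra-assay CV (keeping
concentrations positive), and detection-limit flagging. RNG streams are
split per subject (and per marker), so enlarging a simulated study never
perturbs earlier subjects' draws.

Defaults encode the study conditions: 24 subjects, loads −1/0/+1,
timepoints t-1…t3, and a response decay profile of (1, 0.5, 0.2) across
t1/t2/t3 — a peak immediately post-test relaxing towards baseline within
an hour, the dominant published pattern for the fast markers. Per-marker
baselines and CVs are order-of-magnitude values for serum ELISA panels in
healthy adults; response parameters mirror the qualitative pattern of the
reference study (strong transient COMP/MMP-3 responses with positive
slopes, delayed IL-6 rise, heterogeneous MMP-9 without average response,
flat C2C/CPII). The generating intercept–slope correlation defaults to 0;
the benchmark power scenario does not state one.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: day-to-day baseline drift and circadian
variation (t0 equals the subject's latent baseline on every test day),
assay plate effects and inter-assay variation, missingness other than
detection-limit flagging, and non-normal (e.g. skewed or heavy-tailed)
response distributions. Parameter-recovery results on synthetic data are
therefore best-case.

## The power benchmark

`run_power_study()` reproduces the design's sample-size reasoning: under
the scenario of clinical interest (μ_α = σ_α = μ_β = σ_β = 5, n = 24,
1000 replicates), it simulates, fits and tests each replicate and reports
the four rejection rates with Monte Carlo SEs, at residual SD 5 and 7.
Within the mixture-χ² formulation adopted here (correlated random effects;
variance + covariance removed per test) the σ_β test is the least powerful
of the four — the slope design column carries less information than the
intercept column (squared norms 2 vs 3 per subject) — and its power is
sensitive to the exact boundary reference and to the generating
correlation, neither of which the benchmark scenario pins down. Published
rates for such benchmarks can therefore differ by several points for the
SD parameters even when the mean-parameter rates agree to a point; the
package reports its own rates with their MC uncertainty rather than
calibrating to any external number. Replicates that fail to converge are
excluded and counted (with a warning above 5%); in practice convergence
failures are absent at these sizes.

Problem sizes used in the shipped checks: the acceptance computation runs
the two benchmark scenarios at the full 1000 replicates; the routine test
suite uses 100–300-replicate runs for determinism, calibration and
monotonicity properties, and n = 500 subjects for single-fit parameter
recovery (10% relative error for means, 15% for SDs).

## Known limitations

* One grouping level (subject); no crossed or nested random effects, no
  heteroscedastic residuals by load or timepoint.
* The Wald-normal reference slightly understates mean-test p-values at
  small n compared with a t-type reference.
* Profile SD intervals are mixture-calibrated (see above) and mildly
  conservative for interior values.
* The bootstrap Fisher-z interval assumes approximate normality of the
  z-transformed averaged Spearman statistic; at n = 24 subjects with
  strong true correlation the interval can be slightly asymmetric in
  coverage.
* Censored concentrations are flagged and excluded by rule, not imputed.
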