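# mechmarker

Is a blood biomarker *mechanosensitive* — does its serum concentration
respond to mechanical loading of articular cartilage — and does that
response depend on *how much* load is applied? `mechmarker` implements a
two-stage experimental-analytical framework for answering both questions
from a crossover walking stress test: subjects walk 30 minutes at each of
three ambulatory loads (80, 100, 120% body weight on separate days), with
serum sampled twice before (t-1, t0) and three times after (t1, t2, t3)
each bout. The package is aimed at researchers designing or analyzing such
loading experiments for cartilage markers (COMP, MMP-3, MMP-9, ADAMTS-4,
PRG-4, IL-6, C2C, CPII and the CPII/C2C synthesis/degradation ratio), but
the machinery is marker-agnostic.

## The model

Concentrations are first turned into change-from-baseline values. Two
scales are supported:

* **absolute** — (y_t − y_0)/m × 100, where m is the marker's baseline
  median pooled over subjects and loads, so five points mean a change of 5%
  of a typical baseline level (markers with order-of-magnitude
  within-subject spread, ADAMTS-4 by default, are log10(1+x)-transformed
  first);
* **shifted relative** — (y_t − y_0)/(y_0 + c) × 100, where the per-marker
  constant c ≥ 0 is the smallest shift capping the maximal relative change
  at t1/t2 at 75%, stabilizing ratios when baselines approach zero.

With loads coded l ∈ {−1, 0, +1}, the change value of subject i at load l
is modelled as

    δ_il = α_i + β_i·l + ε_il,   (α_i, β_i) ~ bivariate normal

fitted by REML. Four quantities summarize a marker × timepoint: μ_α and
σ_α (average response at 100% body weight and its inter-individual
variation) and μ_β and σ_β (average dose-response slope per load level and
its variation). Means are tested by Wald tests; the SDs sit on the
boundary of the parameter space and are tested by likelihood-ratio tests
against a 50:50 mixture of χ² distributions, with profile-likelihood
confidence intervals inverted from the same mixture.

The **criteria gate** then mirrors the framework's flow diagram:
criterion I (marker responds: μ_α or σ_α significant at 5%) selects
marker × timepoint combinations; criterion II (response depends on load:
μ_β or σ_β significant) grades the selected set; a marker is *suitable*
for dose-response work if any selected combination passes criterion II.
Interrelationships among suitable markers are quantified by load-averaged
Spearman correlations of the change values (bootstrap + Fisher-z
inference) and plain Spearman correlations of the per-subject slopes.

## Worked example

```r
library(mechmarker)

# simulate the full study design: 24 subjects, 3 loads, duplicates, 8 markers
cfg <- sim_config(n_subjects = 24, seed = 42)
res <- run_pipeline(config = cfg, seed = 42)
res
#> <mechmarker_result>
#>   9 markers, 24 subjects, gating scale: relative
#>   criterion I: 18 combination(s) selected
#>   criterion II suitable: C2C, COMP, CPII, CPII/C2C, MMP-3

# one marker x timepoint in detail
panel <- average_duplicates(simulate_concentration_panel(cfg))
changes <- build_change_table(panel, scale = "relative")
fit <- fit_response_model(changes, marker = "COMP", timepoint = "t1")
fit
#> <response_fit> COMP @ t1 [relative scale]
#>   24 subjects, 72 observations; converged: TRUE
#>   response  mean 28.04 [22.74; 33.34] p=3.366e-25 | SD 12.45 p=1.29e-08
#>   slope     mean 4.40 [1.77; 7.03] p=0.00103 | SD 3.53 p=0.1509
#>   residual SD 7.83; random-effect correlation -0.62
tidy(fit)
```

The simulated COMP analog responds strongly at t1 (mean relative change
≈ 28% of baseline with clear inter-individual variation, SD ≈ 12) and
shows a positive average dose-response slope (≈ 4.4 points per load
level), so it passes criteria Ia/Ib and IIa — the behaviour its
generating parameters encode.
Power for the benchmark design is available directly:

```r
run_power_study(sim_config(seed = 1), n_reps = 1000, seed = 7)
# rejection rates for mu_alpha, sd_alpha, mu_beta, sd_beta at the 5% level
```

A worked gating example on the published summary tables of a 24-subject
reference study ships with the package:

```r
gates <- apply_criterion_one(
  reference_fit_table("response"),
  overrides = tibble::tibble(marker = "PRG-4", timepoint = "t2",
                             reason = "isolated negative mean response"))
apply_criterion_two(reference_fit_table("slope"), gates)$verdicts
```

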