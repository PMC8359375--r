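# toxmatrix

Direct toxicity assessment (DTA) asks whether a real environmental
sample — here, contaminated groundwater adjusted to marine salinity and
tested on marine invertebrates — harms biota as a whole mixture, without
attributing the effect to individual chemicals. The raw material is
time-course survival: cohorts of 10 individuals per replicate vial (5
replicates per test solution, 6 per control) counted on a few
observation days over a 14- or 21-day static press exposure. Outcomes
are often partial, so a single fitted curve is frequently not enough to
call a result.

`toxmatrix` is an R package for ecotoxicologists and environmental
risk assessors that implements both halves of that analysis:

1. **Lethal-time modelling.** Log-logistic and Weibull time–response
   curves, in the standard dose–response parameterization
   `f(t) = c + (d − c) / (1 + exp(b(ln t − ln e)))^f` (and the Weibull
   analogues), fitted to replicate-level percent survival by
   least squares; model choice by AIC among six families
   (`LL3u100`, `LL3`, `LL4`, `LL5`, `W14`, `W24`); inversion of the
   selected curve to `LT10`/`LT50` — for the log-logistic,
   `LT_p = e (p/(100−p))^{1/b}` — with delta-method 95% confidence
   limits.
2. **Weighted response matrix.** Five weight-of-evidence criteria
   (visual distinctness from both controls; end-survival difference
   ≥ 20 points vs the brine control; end survival < 80%; LT10 CI
   separation; LT50 CI separation), each scored 1 / 0.5 / 0 and
   weighted 4 / 3 / 2 / 1 / 1. The response score
   `100 Σ wᵢsᵢ / Σ wᵢ` classifies a species × test-solution × round
   combination as **Response** when it reaches 65%. Summaries give
   "% toxic" per solution and "% toxic response" per species, with
   external assay results (Microtox EC50 bands) alongside.

A synthetic-trial generator (latent individual death times, immune
fractions for background control mortality, hierarchical seeding) makes
every stage testable against known truth, including parameter-recovery
experiments with CI-coverage reporting.

## Worked example

Simulate one toxic test solution against brine and seawater controls,
fit the candidate families, and derive lethal times:

```r
library(toxmatrix)

cfg <- synthetic_config(
  groups = list(
    synthetic_group("TS1", lt50 = 6, shape = 4),
    synthetic_group("HSB", immune = 0.8, lt50 = 30, shape = 2, n_replicates = 6),
    synthetic_group("SW",  immune = 0.9, lt50 = 30, shape = 2, n_replicates = 6)),
  seed = 11)
x <- generate_trial(cfg)

best <- select_best(fit_models(replicate_survival(x, "TS1")))
best
#> LL3u100 fit
#>      b      e
#> 4.2860 5.8876
#> rss = 2087.8  n = 30  AIC = 133.28
estimate_lt(best, 10)
#> LT10 = 3.5 d (95% CI 3.0 to 4.1)
estimate_lt(best, 50)
#> LT50 = 5.9 d (95% CI 5.5 to 6.3)
```

The AIC-best family is the upper-asymptote-fixed log-logistic
(`LL3u100`), its inflection `e` ≈ 5.9 days is the fitted median lethal
time (truth: 6), and the LT50 interval of 5.5–6.3 days sits well inside
the 14-day test — strong evidence of response. Scoring a borderline
case by hand: criteria scored (1, 0.5, 1, 0, 0) with the default
weights give

```r
sc <- response_score(c(1, 0.5, 1, 0, 0))
sc$rounded
#> [1] 68
classify_response(sc$unrounded)
#> [1] "Response"
```

— a 68% response score, just above the 65% threshold: a Response
carried by the raw-data criteria even though neither lethal-time
interval separates from the control.

The end-to-end path is `run_pipeline(pipeline_config(input = "survival.csv"))`,
which writes the LT table, the response matrix, the toxicity summaries,
a JSON fit bundle, a Markdown report and a reproducibility manifest.
The numbered scripts under `analysis/` walk the same pipeline as a
narrative: simulate a two-round campaign with planted truth, fit and
tabulate lethal times, score the matrix (on the planted campaign it
flags exactly the 12 strongly toxic cells and none of the 28 inert
ones), summarize relative toxicity, and run a parameter-recovery
experiment.

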