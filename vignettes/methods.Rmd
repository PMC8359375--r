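---
title: "Lethal-time modelling and the weighted response matrix: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lethal-time modelling and the weighted response matrix: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxmatrix)
```

## The assessment problem

Direct toxicity assessment (DTA) exposes local biota to a real
environmental sample — in the motivating application, groundwater from
remediated fuel-spill sites adjusted to marine salinity with hypersaline
brine (HSB) — and asks whether the mixture, as a whole, harms them. The
test design is a static press exposure: a fixed cohort of 10 individuals
per replicate vial, 5 replicate vials per test solution and 6 per
control (HSB and natural seawater, SW), observed on a handful of days
over a 14- or 21-day test. Many outcomes are partial: some mortality,
but no clean 0-to-100% response over the observation window. `toxmatrix`
implements the two analysis stages this situation needs — time–response
modelling where the data support it, and a weighted multi-criterion
decision rule where they do not.

## Time–response models

Replicate-level percent survival $y_{rj}$ at day $t_j$ is modelled with
the standard dose–response families, reading exposure *duration* as the
dose axis. In the conventional $(b, c, d, e, f)$ parameterization:

* log-logistic: $f(t) = c + (d-c)\,/\,\bigl(1+e^{b(\ln t-\ln e)}\bigr)^{f}$
  with $f=1$ except in the five-parameter variant;
* Weibull-1: $f(t) = c + (d-c)\exp(-e^{b(\ln t-\ln e)})$;
* Weibull-2: $f(t) = c + (d-c)\bigl(1-\exp(-e^{b(\ln t-\ln e)})\bigr)$.

Six families are tried: `LL3u100` (c = 0, d = 100 fixed; free b, e),
`LL3` (c = 0), `LL4`, `LL5`, `W14`, `W24`. `k` counts *free* parameters,
so `LL3u100` has k = 2: fixing the upper asymptote at 100% encodes the
biological fact that survival starts complete, and costs nothing when
early observations are near 100%.

Fitting is ordinary least squares via Levenberg–Marquardt, with starting
values $e_0 = \text{median day}$, $b_0 = \pm 1$ (sign chosen so the
curve decreases; Weibull-2 decreases for $b<0$), $c_0 = \min y$,
$d_0 = \max y$, $f_0 = 1$, and a deterministic multi-start over
$b_0 \in \pm\{1, 0.5, 5\}$ with the lowest residual sum of squares kept.
The covariance is the Gauss–Newton approximation
$\hat\sigma^2 (J^\top J)^{-1}$ with $\hat\sigma^2 = \mathrm{rss}/(n-k)$,
and $\mathrm{AIC} = n\ln(\mathrm{rss}/n) + 2(k+1)$, counting the
residual variance as a parameter. Flat data (zero response variance),
optimizer failure, or a singular Gauss–Newton matrix yield
`converged = FALSE`; such groups are *non-modellable*, which downstream
is information, not an error.

Model choice is lowest AIC among converged fits, with ties broken by
fewer parameters and then a fixed family order
(`LL3u100 < LL3 < LL4 < W14 < W24 < LL5`). This automates a
visual-plus-AIC selection practice into something reproducible; on data
generated from `LL3u100` truth the rule returns the generating family
(or `LL3` with $\hat d \approx 100$) in the clear majority of runs.

### Lethal times and their intervals

$LT_p$ is the duration at which survival has declined by $p$% —
interpreted by default relative to the fitted asymptote range
($f(t) = d - \tfrac{p}{100}(d-c)$), with an absolute variant
($f(t) = 100 - p$) available by argument; the two coincide for
`LL3u100`, the family that dominates selection. All families invert in
closed form (e.g. $LT_p = e\,(p/(100-p))^{1/b}$ for the log-logistic),
and the closed forms are tested against bisection on the curve to
1e-8. Confidence limits use the delta method on the natural scale with
a $t$ quantile at $n-k$ degrees of freedom; a noisy, shallow fit can
therefore produce a negative lower limit, which is reported as-is
rather than truncated. Fits whose slope points the non-toxic way
(survival increasing) are flagged and excluded from LT estimation.

### What the intervals do and do not deliver

Treating every replicate × day point as an independent Gaussian
observation uses all the data and matches how percent-survival effects
data are usually fitted, but it ignores that the same 10 individuals
are counted repeatedly: within a replicate, survival at day 10 is
strongly correlated with survival at day 7. The point estimates are
essentially unaffected (in the recovery experiment below, median
relative LT50 error is ≈6% under the realistic cohort generator), but
the independence assumption understates the standard errors, and the
nominal 95% delta-method intervals cover the true LT50 in only ≈70% of
simulated trials under that generator. Under iid Gaussian noise — the
regime the covariance formula actually assumes — coverage is ≈95%,
confirming that the shortfall is a model-assumption effect, not an
implementation defect. This is a known limitation of the
curve-on-percent-survival approach; interval-censored time-to-event
likelihoods would repair it but are outside this package's scope. The
weighted response matrix is, in part, the practical answer: it never
relies on a single interval.

## The weighted response matrix

Five criteria are scored 1 (met), 0.5 (borderline/unclear) or 0 (not
met) for each species × test solution × round:

| # | Criterion | Weight |
|---|-----------|--------|
| 1 | Time course in the test solution distinct from both HSB and SW controls at ≥ 1 day | 4 |
| 2 | End-of-test mean survival difference (HSB − TS) ≥ 20 points; 15–20 borderline | 3 |
| 3 | End-of-test mean survival < 80%; 80–85 borderline | 2 |
| 4 | TS LT10 95% CI entirely below the HSB control's LT10 CI; borderline if the TS upper limit is inside the control range while the TS estimate is below the control lower limit | 1 |
| 5 | As criterion 4, for LT50 | 1 |

The response score is $100\sum w_i s_i / \sum w_i$; with the default
weights $(4,3,2,1,1)$ attainable scores lie on a lattice of halves of
$100/11$. A combination is classified **Response** when the unrounded
score reaches the 65% threshold. Rounding (nearest integer, halves away
from zero) is applied only for reporting.

Boundary conventions, where the verbal rules leave room: criterion 2 is
met at exactly 20 and borderline at exactly 15; criterion 3 is
borderline at both 80 and 85 (85 is pinned borderline by the worked
excerpt shipped in `extdata/response_excerpt.csv`). Criterion 1 is, in
the original assessment, a visual judgment; the automatic rule here
scores 1 when the test-solution mean falls below *both* control means
by ≥ 20 points at any observation day (15–20 borderline), mirroring
criterion 2's magnitudes, and a manual-override channel
(`read_criterion_overrides()`) lets recorded judgments replace any
automatic score. When the HSB control is non-modellable — no control
mortality, hence no control LT — criteria 4/5 fall back to scoring 1
only if the test solution's LT upper limit lies within the test
duration: a control with no estimable lethal time behaves as "beyond
test end". All margins, weights and the threshold are configurable for
sensitivity analysis; one worked excerpt row in the bundled data prints
a score of 93 whose own criterion scores evaluate to 91 under the
formula, and the package reproduces the formula, not the typo.

Summaries pool both rounds: "% toxic" per test solution is the percent
of tested units (species plus external assays such as Microtox) with a
Response; "% toxic response" per unit is the same across solutions;
untested cells leave the denominator. Microtox 15-min EC50 values (as
percent dilution) are banded `≤25` extremely toxic, `(25, 50]` highly,
`(50, 75]` moderately, `(75, 100]` slightly, `>100` no measurable
toxicity — the printed band edges overlap at 25, resolved here as
half-open intervals with the extreme bound inclusive.

## The synthetic generator

`generate_trial()` draws, per individual, an immunity flag (probability
$\pi$) and otherwise a latent log-logistic death time with survival
$S(t) = 1/(1+(t/e^*)^{\beta^*})$, then counts survivors at the
scheduled days. Latent death times — not day-wise binomial thinning —
are the honest emulation of a static press exposure of a fixed cohort,
and they make within-replicate counts exactly non-increasing. Control
mortality is emulated with a high immune fraction (e.g. $\pi = 0.8$
with a finite $e^*$, matching ≈78–80% control end survival) rather
than a separate hazard. Expected percent survival is
$100(\pi + (1-\pi)S(t))$, which the empirical mean approaches at the
binomial rate. The seed drives a hierarchical stream keyed by group
label and replicate, so adding a group never perturbs another group's
draws.

What the generator does *not* emulate: between-replicate
heterogeneity, recounting noise, round-to-round environmental drift,
or any chemistry covariates. Tests passing on this generator therefore
validate the estimation and decision machinery under the model's own
assumptions (plus the cohort correlation discussed above), not the
field realism of any particular dataset.

`recover_parameters()` wraps the loop generate → fit `LL3u100` →
LT10/LT50 → compare to the known truth, reporting bias, RMSE, median
relative error and CI coverage, counting non-convergent replicates
rather than raising. The problem sizes used in the shipped experiments
(500 simulations in the acceptance run, 200 in `analysis/05_recovery.R`,
30–50 in the unit tests) keep each experiment in the seconds-to-minutes
range while leaving Monte-Carlo error well inside the asserted margins.

## Workflow

The `analysis/` scripts are thin numbered drivers over the package:
`01_simulate.R` (a two-round campaign with planted truth),
`02_fit_lt.R` (fits and the LT table), `03_response_matrix.R` (the full
weighted assessment; on the planted campaign it flags exactly the toxic
cells and no others), `04_summarize.R` (relative-toxicity summaries,
Microtox banding, brine mass-balance `dilution_fraction()` — the
fraction of original sample after salinity adjustment,
$(s_\mathrm{brine}-s_\mathrm{target})/(s_\mathrm{brine}-s_\mathrm{sample})$),
and `05_recovery.R`. `run_pipeline()` performs read → fit → score →
classify → summarize → report in one call, logs every non-modellable
group and every manual override, writes fixed-precision CSVs (scores as
integers, lethal times to 1 decimal) so re-runs are byte-identical, and
emits a manifest with input hashes and the echoed configuration.
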