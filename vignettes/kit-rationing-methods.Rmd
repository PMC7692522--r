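---
title: "Rationing rapid diagnostic kits across an epidemic season: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rationing rapid diagnostic kits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kitration)
```

## The problem

A clinic opens an influenza season with a fixed stock of `W_init` single-use
rapid diagnostic kits and no possibility of resupply. Suspected patients
arrive week by week; testing one consumes one kit. When expected demand
exceeds the stock, first-come first-served exhausts the kits mid-season and
biases every downstream statistic toward the early epidemic. The alternative
studied here is *probabilistic* rationing: in week `t` each suspected
patient receives a kit with probability `r_t < 1`, the *consumption rate*.
A good policy keeps `r_t` roughly constant (uniform sampling of patients,
equal access) while ending the season with neither a mid-season stock-out
nor a pile of unused kits.

Notation: the season has `T` weeks (21-25 in the data this package
emulates); `P_t` is the observed count of new suspected patients in week
`t`; `W_t` is the unspent stock at the *start* of week `t`. Strategies
activate at week `t0 = 5` (the forecaster needs five weeks of data), so
`W_5 = W_init` for every strategy and the first week on which strategies
can differ is week 6.

## The four policies

**Ideal benchmark (I).** With hindsight knowledge of all future demand,

$$r^I_t = \min\left\{\frac{W^I_t}{\sum_{s=t+1}^{T} P_s},\ 1\right\},
\qquad
W^I_{t+1} = \max\{W^I_t - \lfloor r^I_t P_t \rfloor,\ 0\},$$

with `r = 1` once no demand remains. This spreads the stock evenly over the
remaining patients; it cannot be deployed (the future is unknown) and
serves purely as the reference trajectory.

**Prediction-based (M).** Identical recursion, but the true future demand
in the denominator is replaced by $\sum_{s=t+1}^{T} \hat P_s(t)$, the sum
of rolling forecasts from the incidence-curve fit described below. When the
forecasts are exact, M *is* I — `run_main()` with an oracle forecast matrix
reproduces `run_ideal()` identically, which the test suite checks on a
thousand random instances.

**Half-stock heuristic (S1).** Spend `min(floor(W_t / 2), P_t)` each week.
No forecasting at all; geometric spend-down.

**Even-split heuristic (S2).** Spend `min(floor(W_t / (T - t)), P_t)`,
i.e. an equal share of the stock for each remaining week (the final week
spends whatever demand absorbs). Uses only an advance estimate of `T`.

Consumption is deterministic expected-value flooring by default, matching
the printed recursions; `apply_week(mode = "stochastic")` instead draws
binomial kit usage at the same rate, for simulating the per-patient lottery
a deployment would actually run. The stochastic mode is excluded from the
evaluation metrics, which are defined on the deterministic recursions.

## The loss metric and the filling rate

A strategy `X` is scored by how far its stock trajectory strays from the
ideal one:

$$E^X = \frac{1}{(T-5)\,W_{\mathrm{init}}}
        \sum_{t=6}^{T} \left|W^X_t - W^I_t\right|.$$

`E = 0` means indistinguishable from the ideal; over-spending early and
hoarding both inflate it. Because both trajectories live in
`[0, W_init]`, `E` never exceeds 1; when the ideal spend-down is roughly
linear across weeks 6..T, the worst attainable value is about 1/2 (a
strategy that spends instantly, or never, differs from a linear ramp by
half the stock on average). That ½ ceiling is *not* a theorem: if demand
collapses shortly after activation (a sharp, early peak with an empty
tail), the ideal spends everything at once while S2 — capped by
`floor(W/(T-t))` and by zero weekly demand — never spends, and `E`
approaches 1. The test suite's calibrated-ensemble bound check documents
exactly this: strategies M and S1 stay below ½ there, S2 does not on
early-peak institutions.

The severity of the shortage is summarised by the *filling rate*
`f = W_init / sum(P_t)`; `f = 1` means one kit per suspected patient.
`filling_to_stock()` inverts it by nearest-integer rounding (base R's
`round()`, i.e. half-to-even; the convention matters only at exact .5
products) with a floor of one kit. `sweep_filling_rates()` runs every
institution over a grid of `f` values and summarises losses per volume
group with linear-interpolation quartiles and the standard 1.5 x IQR
outlier rule; `find_min_loss_fill()` then locates each institution's most
efficient stock level and reports whether it is *interior* (strictly below
the top of the grid) — the pattern that makes prediction-based rationing
worthwhile, since it means a clinic can deliberately buy fewer kits than
patients and lose nothing by it.

## The forecasting model

Weekly incidence is modelled by the closed-form single-peak wave of the
Kermack-McKendrick SIR model,

$$\hat P(t) = \max\{0,\ A\,\mathrm{sech}^2(b\,t + c) + p\},$$

with amplitude `A > 0` (patients/week), rate `b > 0` (1/week), shift
`c <= 0` putting the peak at week `-c/b`, and a baseline `p` in `[-1, 1]`
absorbing sporadic off-season cases; negative raw values are clamped to
zero. Fitting minimises the sum of squared residuals under box
constraints. Default boxes are `A` in `(0, 3 x max observed count]`, `b`
in `[0.1, 2]`, `c` in `[-10, 0]`, `p` in `[-1, 1]` — wide enough to cover
the per-institution fits observed across a city's surveillance network,
whose extremes sit at exactly these edges.

Numerical choices. The optimiser is `stats::optim(method = "L-BFGS-B")`
restarted from a fixed 4 x 4 grid over `(b, c)` (amplitude started at the
observed maximum, baseline at zero), keeping the best of all starts; there
is no randomness, so refitting the same data is bitwise reproducible. Ties
between starts resolve to the first in grid order. An all-zero prefix
carries no signal and returns a flagged boundary fit predicting zero. On
noiseless 25-week curves the fit recovers all four parameters to within
0.05% relative error (the suite asserts 1%).

`rolling_forecasts()` refits on each prefix `1..t` (`t = 5..T-1`) and
predicts weeks `t+1..T`, mimicking what a clinic could compute in week
`t`; strategy M's denominator is the corresponding row sum. Before the
peak enters the fit window the amplitude is fundamentally unidentifiable —
a rising prefix constrains `A` only through the box — so forecast error is
allowed to fluctuate there; from the first fit week at or after the peak,
the total absolute forecast error is non-increasing (the suite permits
sub-patient wobble of < 1, the quantum introduced by integer-rounded
counts). We deliberately share one box across all rolling fits rather than
shrinking `A` to each prefix's maximum: the box encodes season-scale prior
knowledge, which is exactly what a deploying clinic would have.

The SIR basic reproduction number is representable on fitted parameters
(`r0_estimate`) but is not computed by this package; it plays no role in
any rationing decision.

## The synthetic season generator

No institution-level surveillance series ships with the package; the
generator replaces it. `synthetic_config()` defaults describe one season
of city-wide influenza surveillance: 38 institutions over `T = 25` weeks,
split 13/13/12 into volume groups A/B/C, with curve parameters drawn
uniformly and independently within per-group ranges taken from full-season
fits to such data (group A amplitudes 22.6-124.4 patients/week, B
13.7-58.5, C 1.6-17.6, with correspondingly broader rate ranges for the
small institutions). Where a published extreme sits exactly on a
fitting-box edge — evidence of an active constraint, not of the underlying
epidemiology — the sampling range is pulled slightly interior
(`c`: -10 to -9.9, `b`: 2.0 to 1.95, `p`: +-1 to +-0.99). Draws are
rejected until the peak week `-c/b` lands in `[4, T-4]`, keeping every
season single-peaked and mid-season. Observation noise is Poisson per week
around the curve (the natural choice for count data; `"none"` rounds the
curve instead). Everything is driven by one integer seed and restores the
caller's RNG state; the same configuration is bitwise reproducible.

What the generator does *not* emulate: correlation between `b` and `c`
(real fits cluster their peaks in a narrower mid-season band than the
independent-uniform box does, so the synthetic ensemble contains more
early- and late-peak extremes than a real city), spatial correlation
between institutions, multi-peak seasons, and reporting artifacts such as
holiday dips. Passing tests on these ensembles therefore demonstrates the
engine's correctness and the qualitative strategy ordering, not
quantitative agreement with any particular city's loss values.

## Problem sizes and determinism in the test suite

The slow checks run on a 50-institution, 25-week Poisson ensemble
(17/17/16 across groups, seed fixed in the suite) swept over
`f = 0.4, 0.55, 0.7, 0.85, 1.0` — 750 strategy runs and about a thousand
curve fits, a couple of minutes end to end; recursion-level checks use a
thousand random instances with `T <= 12`, `W_init <= 50`, weekly counts
`<= 20`, against independent line-by-line transcriptions of the four
recursions. The acceptance script regenerates a 38-institution default
season from its `--seed` and recomputes every reported quantity from
scratch.

## Known limitations

- The sech-squared wave cannot represent two-peak seasons; rolling fits on
  such data will chase whichever peak dominates the prefix.
- Pre-peak forecasts are box-limited guesses; strategy M inherits their
  volatility in weeks 5-8, visible as a wider loss spread for small
  institutions.
- Group labels from volume ranking need not match the generating group of
  a synthetic institution near the group boundaries; the package ranks by
  observed totals, as one would with real data.
- The loss compares stock *trajectories*, not patient-level outcomes; two
  strategies with equal `E` may still distribute kits across very
  different patients in stochastic deployment.

## A worked example

```{r example, eval = FALSE}
library(kitration)

ens <- generate_ensemble(synthetic_config(seed = 42))
sw <- sweep_filling_rates(ens, strategies = c("M", "S1", "S2"),
                          f_grid = c(0.4, 0.55, 0.7, 0.85, 1.0))
subset(sw$summaries, group == "A" & f == 0.55)
find_min_loss_fill(sw, "A01", "M")
```
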