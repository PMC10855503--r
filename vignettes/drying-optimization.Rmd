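---
title: "Methods: thin-layer drying kinetics, response surfaces and grey wolf optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thin-layer drying kinetics, response surfaces and grey wolf optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dryopt` re-analyzes a 17-run Box-Behnken drying experiment on yam slices
dried with combined infrared and hot air, and re-runs its multi-objective
process optimization. This vignette is the package's own account of the
models and the choices behind them.

## The experiment and its indicators

Three process factors are varied at three levels each: drying temperature
A (55/60/65 °C), slice thickness B (4/6/8 mm) and infrared radiation
distance C (80/120/160 mm). Six quality indicators are measured per run:
drying time Y1 (min), CIELAB color difference Y2, unit energy consumption
Y3 (kJ·h/kg, kept in the instrumentation's printed unit), polysaccharide
content Y4 (mg/g), rehydration ratio Y5 (kg/kg) and allantoin content Y6
(µg/g). The first three are to be minimized, the last three maximized.
The design is the standard three-factor Box-Behnken layout: 12
edge-midpoint runs plus 5 center replicates, giving pure-error degrees of
freedom for a lack-of-fit test.

## Thin-layer kinetics

Moisture is handled on a dry basis, `M_t = (W_t - G)/G`, and normalized to
the moisture ratio `MR = M_t / M_0`. Thin-layer theory for a slab gives
near-exponential decay, so `ln MR` is regressed on time by OLS and the
effective moisture diffusivity follows from the slab solution of Fick's
second law, `D_eff = slope_per_second · L² / π²`.

Two numerical choices deserve a note:

* **Time unit of the tabulated slopes.** The source tables never state the
  time unit of their `ln MR`–t slopes, and no unit choice reproduces the
  printed (slope, D_eff) pairs through the slab formula with L = 6 mm.
  The pairs *are* mutually consistent with a single constant
  `D_eff = c · slope`, `c ≈ 3.60×10⁻⁸ m²·min`, which the package exposes
  as `deff_reference_calibration`. `deff_from_slope()` takes either the
  geometric route (explicit characteristic length and time scale) or that
  calibration. Two tabulated entries resist even the calibration: the
  55 °C diffusivity is printed `9.89e-8` where slope proportionality
  implies `9.89e-9` (an exponent slip), and the 70 °C value breaks
  proportionality outright. The shipped fixture keeps both the printed and
  the recomputed columns; nothing is silently corrected.
* **Characteristic length.** Full slice thickness by default (the tables
  are internally consistent only with a single constant, so the convention
  is configurable but not inferable). Half-thickness — the two-sided-drying
  convention — is obtained by passing `L/2`.
* **Drying-rate abscissa.** Rates between consecutive weighings are
  reported against the interval-midpoint moisture; the source plots DR
  against moisture without stating its convention.

## Response-surface models and ANOVA

Each indicator is fitted to the full second-order polynomial (intercept,
3 linear, 3 interaction, 3 quadratic terms) by OLS. The ANOVA reports,
per term, a partial (Type-III) F with 1 numerator and 7 denominator
degrees of freedom — computed in *coded* units, the response-surface
software convention; in actual units the polynomial columns are heavily
correlated and the partial tests would answer a different question. The
residual is split into lack of fit (3 df) against pure error from the five
center replicates (4 df). `C.V.% = 100·√MSE / ȳ` is the model's relative
noise measure. The refits reproduce the published per-indicator R²
(0.9497 … 0.9881), model F values and C.V.% exactly at the printed
rounding.

Pruning keeps the intercept plus every term with p < 0.05 and refits.
Model hierarchy is deliberately **not** enforced: the published reduced
equations keep interactions without their parent quadratics (the
drying-time equation retains AC and BC but no A²), and the refit
reproduces those published coefficients to the printed digits. `alpha` is
an argument; 0.05 is the study's convention.

## Indicator weights and the composite fitness

Weights come from the coefficient of variation across the 17 runs:
`V_i = σ_i / x̄_i`, `W_i = V_i / ΣV_i`, with the **population**
(divide-by-n) standard deviation — the only convention that reproduces the
published drying-time SD of 32.64 (the n−1 value is 33.64). The composite
scalarized objective is

```
f(x) = Σ w_i (1 − k_i)²,   k_i = f_best/f_act (minimize) or f_act/f_best (maximize)
```

anchored to the single-objective bests. `k_i > 1` (a candidate beating the
recorded best) is left unclamped; the quadratic handles it smoothly.

## What the single-objective "bests" actually are

A finding of this re-analysis: the published best drying time of
136.37 min is *not* the box minimum of the drying-time model. The refit
full quadratic attains 112.9 min at the hot/thin/close corner (65 °C,
4 mm, 80 mm; verified against a 201³ grid), and the published reduced
equation goes lower still. The published 136.37 is the model's prediction
at the published interior optimum (63.41 °C, 4.58 mm, 81.04 mm) — the
output of a desirability search, which stops anywhere past the observed
response floor. The package reproduces 136.37 to 0.02% as
`predict(model, reference_settings)` and reports both that number and the
true box minimum; the acceptance machinery checks the optimizer against
the dense-grid oracle, which is the well-defined part of the computation.

## Grey wolf optimization

Single-objective: each candidate ("wolf") moves to the equal-thirds
combination of three leader-guided points
`X_i = X_leader − A_i·|C_i·X_leader − X|`, with `A ~ U(−a, a)`,
`C ~ U(0, 2)` drawn per wolf per dimension and `a = 2(1 − k/k_max)`
decaying linearly. Positions are clipped to the box (reflection was
considered and rejected: clipping concentrates candidates on active bound
faces, which is where corner optima of quadratics live). Leader ties break
by lowest index, making runs fully seed-reproducible.

One structural caveat documented up front: the update's residual
perturbation scales with `|X_leader|`, so ultra-tight convergence (1e−6)
is only observed for optima near the origin of the coordinate frame. On
the drying box the optimizer still lands exactly on the grid-oracle
minimum because the optimum sits on a corner that clipping makes
absorbing.

Multi-objective: an external archive (capacity 100) stores mutually
non-dominated solutions. The archive strategy — left unspecified by the
source beyond "update and deletion operations according to a particular
strategy" — is the standard hypercube design: an adaptive grid with 10
divisions per objective, leader selection by roulette over sparse cells
(probability inversely proportional to occupancy), and overflow deletion
from the most crowded cell. Default budgets follow the study: population
100, archive 100, 1000 iterations.

## Pareto post-processing

The source selected "ten sets from the ellipse" of its Pareto plot by eye.
The package replaces that with a documented rule: rank archive members by
the composite fitness and average the 10 best coordinate-wise
(`pareto_select_average()`). A second finding follows: the composite
fitness built from the published weights and bests has its box optimum
near (57 °C, 5.3 mm, 138 mm) — the low-color-difference region — *not* at
the published recommendation (63.57 °C, 4.27 mm, 91.39 mm), which leans
toward the fast-drying corner of the front. The two rules genuinely
disagree; the package therefore reproduces the published recommendation
the way it is defined — as the coordinate-wise average of the published
10-row Pareto set, shipped as a fixture — while its own pipeline
recommendation follows the documented fitness-ranking rule.

## Neural surrogate

One network per indicator (3 inputs → H sigmoid hidden nodes → 1 linear
output), rather than a single 3-H-6 net: the source describes both "3-m-6"
and "4-8-1" topologies, and per-response nets are what make per-response
fit metrics well defined ("4-8-1" implies a fourth input that does not
exist among the three factors; it is implemented as 3-H-1). Training is
full-batch backpropagation with momentum on min-max normalized data,
weights initialized U(−0.5, 0.5) under an explicit seed, an 80/20 seeded
row split (14/3), and early stopping on the best-so-far training loss.
Defaults (learning rate 0.3, momentum 0.9, ≤ 20 000 epochs, patience
1000) were fixed once on noiseless generator truth, where an 8-node net
reaches all-data R² ≥ 0.999 in under a second. The hidden size is chosen
by scanning 3–13 and maximizing mean test R²; the additive `N + L + a`
rule is exposed for completeness but the scan is the operative mechanism.
Published surrogate metrics are treated as non-reproducible: training 17
points through a stochastic split and initialization does not admit
run-for-run reproduction, so the suite asserts determinism-under-seed and
capacity-on-truth instead, and the published metrics feed only
deterministic arithmetic (e.g. the 61.34% RMSE reduction).

## Synthetic data: what it emulates and what it does not

`simulate_drying_curve()` inverts the thin-layer model: exponential MR
decay with the rate log-linearly interpolated per factor from the
tabulated one-factor sweeps (slopes read as per 15-min weighing interval,
which places simulated drying times inside the observed 150–255 min
range), masses back-computed from a 150 g load at 5.362 g/g initial
moisture, multiplicative Gaussian weighing noise (SD 0.2%), truncation at
0.13 kg/kg wet-basis moisture. The cross-factor rate surface is a
separable convenience — the experiment only measured one-factor sweeps —
so the generator is faithful per axis and merely plausible off-axis.

`simulate_bbd_table()` adds Gaussian noise with
`σ_j = C.V.%_j · mean(truth_j)/100` to the reference reduced surfaces,
using the tabulated per-model C.V.% (5.5, 3.56, 4.83, 5.71, 1.87, 2.01).
Noise is homoscedastic per response. Passing tests on these tables shows
the estimators recover quadratic surfaces under calibrated Gaussian noise;
it does not validate the quadratic form itself against a real dryer, nor
any non-Gaussian or heteroscedastic measurement behavior.

## Problem sizes used by the checks

The test suite runs the full 17-run fits everywhere; simulation-based
properties use 100–200 replicate tables; optimizer properties use packs of
20–40 wolves for 80–250 iterations; the acceptance script's
multi-objective run uses population 100, capacity 100 and 400 iterations,
and its grid oracle 201³ points. These sizes are the package's choices for
desk-scale reproducibility; the optimizer defaults remain the study's
(100/100/1000).

## Known limitations

* The kinetics module fits only the simple exponential (log-linear) thin
  layer model; Page-type families, shrinkage corrections and Arrhenius
  activation energies are out of scope.
* Quantities whose unit bookkeeping the source omits (cuvette
  concentration → mg/g solids, the kJ·h/kg energy unit) are passed through
  with explicit user-supplied conversions rather than guessed.
* The optimizer handles box constraints only.
* With 17 rows, surrogate test metrics are fragile; treat them as
  diagnostics, not model selection evidence.
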