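---
title: "Factorial formulation analysis and shelf-life kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorial formulation analysis and shelf-life kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petitsuisse)
```

## The problem

A formulator varying two functional ingredients — a prebiotic fiber (inulin)
and a hydrocolloid thickener (xanthan gum) — in a fermented dairy gel wants
to know three things: how each ingredient drives the product's composition
and texture, which combination best balances several competing quality
targets, and how stable the product's probiotic population and gel structure
are over refrigerated storage. The package covers that workflow for 2^k full
factorial designs with center points, and ships the reference seven-run
buffalo Petit Suisse study (a 2² design with three center replicates) it was
validated on.

## The response model

Factors are handled in *coded units*: `x = (u - center) / half_range`, so
the low, center and high settings map to exactly −1, 0 and +1
(`encode_level()` anchors those three points exactly, so balanced designs
stay orthogonal in floating point). Each response is fitted with the
first-order model with interaction

$$y = b_0 + b_1 x_1 + b_2 x_2 + b_{12} x_1 x_2 + \varepsilon,$$

by least squares on the coded model matrix. Two properties motivate fitting
in coded space and expanding afterwards:

* on a balanced 2² + center design the coded columns are orthogonal, so
  $b_0$ is the grand mean and $b_1, b_2, b_{12}$ are the factorial
  contrasts divided by 4 — numerically stable and directly interpretable;
* the physical-unit coefficients then follow from exact algebra
  (`coded_to_physical()` substitutes the affine coding maps and collects
  terms), so predictions are identical in both parameterizations (the test
  suite checks this to 1e−9 relative, and checks the coded fit against both
  a closed-form contrast oracle and `lm()`).

With seven runs the fit has 3 regression and 3 residual degrees of freedom;
the ANOVA identity SSR + SSE = SST holds by construction,
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$, and the overall F test uses the exact
F distribution (`stats::pf`). Two degenerate cases are flagged rather than
silently numbered: a response constant across runs reports $R^2 = 0$ with
`constant_response = TRUE` (the conventional choice; 0/0 is undefined), and
an exact interpolation (SSE = 0) reports `saturated = TRUE` with `p = NA`.

On the packaged dataset this reproduces the study's own models — e.g.
firmness (N):

```{r firmness}
fit <- fit_first_order(petit_suisse_design(), "firmness")
fit
```

Two of the ten responses (consistency and total sugars) are known to have
published coefficient sets that are not self-consistent with the data table
they accompany; the package always reports the refit (the tests document the
agreement, which is within ~2% for all but the total-sugars interaction).

Treatment comparisons outside the regression framework use
`one_way_anova_tukey()`, a thin wrapper over `stats::aov` +
`stats::TukeyHSD` (studentized range, Tukey–Kramer for unequal n) with a 5%
default level, plus explicit handling of the all-identical degenerate case.

## Desirability optimization

The desirability machinery follows Derringer and Suich: each response maps
to $d(y) \in [0,1]$ through one-sided or two-sided power ramps
(`maximize`, `minimize`, `target`, `range`), and the composite is the
weighted geometric mean $D = (\prod d_i^{w_i})^{1/\sum w_i}$, which is 0
whenever any single response is unacceptable. Defaults are linear ramps
(`s = t = 1`) and equal weights — the standard neutral choice when a study
states targets but not shapes; both are configurable per response.

The reference study's targets are: total sugars minimized towards
10 g/100 g, firmness in 3–6 N, viscosity index at 13, cohesivity maximized
towards 1.29 N. Ramp bounds are not part of those targets, so missing bounds
are resolved from each model's prediction range over the search domain
(padded infinitesimally only when a bound would coincide with the target,
to keep every ramp's span nonzero).

Design choices that were genuinely open:

* **Search domain.** The default domain for the packaged study (inulin
  0–20, xanthan 0.3–1.5 g/100 g) extends beyond the tested design box,
  because the desirable firmness band (3–6 N) lies above every prediction
  inside it — the box's fitted maximum is ≈2.1 N. No special case is made
  for that: the firmness desirability is simply < 1 inside the box, which
  pushes the optimum outward, and the result carries an `extrapolated`
  flag. A first-order model extrapolated that far is a direction finder,
  not a quantitative prediction; the flag exists so downstream users treat
  it as such.
* **Optimizer.** Exhaustive grid evaluation (201 × 201 by default) with
  optional Nelder–Mead polish (`stats::optim`) clamped to the domain; the
  refined point is accepted only if it does not lower D. Grid ties break
  towards the smallest factor values, first factor first, so results are
  bit-reproducible. A property test checks the grid argmax against an
  independently coded brute-force evaluation at 21 × 21.

```{r optimum}
res <- petit_suisse_optimization(resolution = 101)
res$optimum
```

## Shelf-life kinetics

Viable-count series (CFU/mL at days 0, 7, 14, 21, 28) are summarized by
first-order kinetics:

* specific death rate $k = \ln(N_0 / N_t) / t$ per day, evaluated over the
  full storage span by default. The division by $t$ is the canonical
  first-order form — it is the only reading that reproduces every published
  rate in the reference table. Negative $k$ means net growth.
* specific growth rate $\mu = (\ln N_t - \ln N_{t_0}) / (t - t_0)$ over the
  exponential window, days 0–14 by default — the window that reproduces all
  seven published values; `growth_window()` offers a data-driven
  alternative (the consecutive-interval log-slope maximizer, extended while
  the slope stays positive) but is off by default.
* survival $= 100 \, N_{\text{final}} / N_0$; survival > 100% is exactly
  equivalent to $k < 0$, and $k$ over $[0, t]$ equals $-\mu$ over the same
  window (both are computed from the same log-difference so the identity is
  exact in floating point, not just algebraically).

```{r kinetics}
kinetics_summary(petit_suisse_viability())
```

The syneresis index is $100 \, W_{\text{whey}} / W_{\text{cheese}}$,
dimensionless and homogeneous of degree zero in the two weights; a gel that
expels no whey scores exactly 0%, stored as a value, not as missing.
`storage_trend()` reduces a pH or titratable-acidity series to its
endpoints, signed change, monotonicity class and extremum day.

## What the synthetic generators emulate

The generators exist so every estimator can be validated by parameter
recovery without external data. They are pure functions of their arguments
plus a mandatory seed (no global RNG state is consumed or left behind):

* `simulate_design_responses()` — the factorial data-generating process:
  the first-order-with-interaction model in physical units plus i.i.d.
  Gaussian noise. σ = 0 makes the fit the exact inverse of the generator.
* `simulate_viability()` — piecewise-exponential counts
  $N(t) = N_0 e^{\int \mu}$ with lognormal multiplicative noise
  (mean-corrected, so counts are unbiased and always positive; plate
  counts cannot go negative, which additive Gaussian noise would allow).
  Piecewise-constant μ phases mimic the rise-then-dip pattern of real
  storage series.
* `simulate_storage_series()` — pH decaying exponentially towards its
  late-storage value, titratable acidity rising complementarily, and
  syneresis following a linear drift truncated at 0, returned as
  whey/cheese weight pairs so the index round-trips.

What they deliberately do **not** model: correlated noise across responses,
plate-count rounding and dilution bookkeeping, lag phases or
Gompertz/Baranyi growth curves, and any mechanistic fermentation chemistry.
Passing recovery tests therefore demonstrates that the estimators invert
the assumed statistical structure — not that real cheese obeys it.

Recovery checks run at three noise levels (σ ∈ {0.2, 0.02, 0}; CV up to
0.05) with the published firmness coefficients as ground truth, using 500
replicate designs and 1000 replicate viability series: means must land
within 3 Monte-Carlo standard errors of truth, and bias must shrink with
the noise. These sizes keep the whole suite under half a minute while
leaving the Monte-Carlo standard errors far below the effects being
recovered.

## Numerical conventions

* Printed-precision comparisons (e.g. a published R² of 0.969559) live only
  in the tests; every function returns full double precision.
* CSV dialect is comma-separated, dot-decimal, UTF-8, one header row; a
  decimal-comma file raises an explicit dialect error rather than a silent
  misparse, and row-level validation errors carry file line numbers.
* `run_full_analysis()` is deterministic given its inputs; stages without
  inputs are recorded as skipped with a reason, and failures halt unless
  `keep_going = TRUE`, in which case they are logged in the report.

## Limitations

* The response model is first-order with interaction: no curvature
  diagnostics (the three center replicates would support a pure-error /
  lack-of-fit split, which is out of scope), no quadratic RSM.
* Desirability results depend on ramp bounds; with auto-resolved bounds
  they depend on the search domain. The shipped defaults are sensible for
  the packaged study but should be set explicitly for new data.
* Kinetics assume first-order behaviour between sampling points; with
  five-point series the rates are descriptive summaries, not fitted growth
  curves.
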