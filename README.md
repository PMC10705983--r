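# petitsuisse

Statistical analysis of two-level factorial formulation studies of fermented
dairy gels — response-surface fitting, multi-response desirability
optimization, and shelf-life microbial kinetics — built around the reference
seven-run buffalo Petit Suisse cheese study (inulin and xanthan gum as
formulation factors) that ships with the package.

## Who it is for

Food scientists and process statisticians running 2² full factorial designs
with center points on product formulations, who need to (i) quantify how
each ingredient drives a set of responses, (ii) find the formulation that
best balances competing targets, and (iii) track probiotic viability and gel
stability over refrigerated storage.

## The models

**Response surface.** Each response is fitted with the first-order model
with interaction on coded factors,

    y = b0 + b1 x1 + b2 x2 + b12 x1 x2,    xi = (ui − center_i) / half_range_i,

by least squares. For a balanced 2² + center design the coded columns are
orthogonal, so b0 is the grand mean and b1, b2, b12 are the factorial
contrasts divided by 4. The coefficients are then expanded algebraically to
physical units (`g/100 g` of ingredient), and the regression ANOVA gives
SSR + SSE = SST, R² = 1 − SSE/SST and the overall F test on (3, n − 4)
degrees of freedom.

**Desirability.** Each fitted response gets a Derringer–Suich desirability
d(y) ∈ [0, 1] (maximize / minimize / target / range ramps), and the composite
D = (∏ dᵢ^wᵢ)^(1/Σwᵢ) is maximized over the factor space by exhaustive grid
search with optional Nelder–Mead refinement.

**Shelf-life kinetics.** From viable counts N(t) (CFU/mL) over storage:
specific death rate k = ln(N₀/Nₜ)/t, specific growth rate
μ = (ln N(t) − ln N(t₀))/(t − t₀) over the exponential window (days 0–14 by
default), percent survival 100·N(final)/N₀, and the syneresis index
100·W_whey/W_cheese.

## Worked example

```r
library(petitsuisse)

design <- petit_suisse_design()
fit <- fit_first_order(design, "firmness")
fit
#> First-order model with interaction for 'firmness' (7 runs)
#> Physical-unit coefficients:
#>      intercept         inulin        xanthan inulin:xanthan
#>   -0.287048000   -0.000333333    0.906667000    0.126667000
#> R^2 = 0.9580, F(3,3) = 22.7933, p = 0.014442
```

Firmness rises by ≈0.91 N per g/100 g of xanthan gum, inulin alone has a
negligible effect (−0.0003), and the positive interaction (0.127) means the
two ingredients stiffen the gel synergistically; the model explains 95.8% of
the run-to-run variation and is significant at p = 0.014.

```r
kinetics_summary(petit_suisse_viability())
#>   trial             k          mu survival
#> 1     1 -0.0015598237 0.003119647 104.4643
#> 2     2 -0.0012107697 0.001823807 103.4483
#> 3     3 -0.0009524374 0.001275544 102.7027
#> 4     4 -0.0027137824 0.004256578 107.8947
#> 5     5 -0.0003232084 0.001287036 100.9091
#> 6     6 -0.0003232084 0.001287036 100.9091
#> 7     7 -0.0003232084 0.001287036 100.9091
```

Every trial has a negative death rate and survival above 100%: the lactic
acid bacteria kept growing in cold storage. Trial 4 (high inulin, high
xanthan) is the most favourable, with μ = 0.00426 day⁻¹ and 107.89%
survival at day 28.

```r
res <- petit_suisse_optimization()
res$optimum
#> Composite desirability optimum
#>   inulin = 9.388 (coded -0.322)
#>   xanthan = 1.278 (coded +4.187)
#>   D = 0.7112 [outside tested design region]
#>   individual d: total_sugars = 0.3591, firmness = 0.7971, viscosity_index = 0.8935, cohesivity = 1
```

The formulation that best balances low sugars, 3–6 N firmness, a viscosity
index of 13 and high cohesivity needs more xanthan gum (≈1.3 g/100 g) than
the tested 0.5–0.8 range — the optimum is an extrapolation, flagged as such.

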