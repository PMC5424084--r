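# exclophys

Leaf gas-exchange and understory-light analysis for herbivore-exclosure
experiments.

Overabundant deer keep forest understories open; fencing them out lets the
herb and shrub layer regrow and darkens the habitat of low-stature plants.
Quantifying that chain — light availability, canopy phenology, and the leaf
physiology that responds to both — takes a specific analysis stack, which
this package provides end to end for paired fenced/unfenced designs:

* **Light-response curves.** Non-rectangular hyperbola
  `A_net(P) = [φP + A_max − √((φP + A_max)² − 4θφP·A_max)]/(2θ) − R_d`,
  fit per curve by multi-start Levenberg–Marquardt
  (`fit_light_response()`), with closed-form light compensation point
  `R_d(A_max − θR_d)/(φ(A_max − R_d))` and 90 % light saturation point
  `9A_max(1 − 0.9θ)/φ`.
* **A/Ci curves.** Farquhar–von Caemmerer–Berry model
  `A_net = min(A_v, A_j) − R_day`, with
  `A_v = V_cmax(C_i − Γ*)/(C_i + K_c(1 + O/K_o))` and
  `A_j = J_max(C_i − Γ*)/(4C_i + 8Γ*)` (defaults K_c = 40.4 Pa,
  K_o = 24.8 kPa, O = 21 kPa, Γ* = 3.7 Pa at 25 °C), all three parameters
  estimated simultaneously (`fit_aci()`).
* **Canopy closure.** Penalized-spline smooth of daily midday sensor PPFD
  with an analytic derivative band; the closure day is the first day after
  the steepest decline at which the slope is statistically
  indistinguishable from zero (`fit_canopy_smooth()`, `closure_day()`).
* **Treatment light divergence.** Linear mixed model of log plant-mean
  PPFD with day + day² + fencing + day×fencing fixed effects, a day random
  intercept, and treatment-specific power-of-day residual variance;
  nested-model likelihood-ratio tests and original-scale treatment means
  (`fit_ppfd_lmm()`, `lr_test()`, `treatment_means_original_scale()`).
* **Trait contrasts.** Seasonal fencing × month ANOVA with within-month
  t-contrasts, mixed-model LRTs per trait with 1/SE precision weighting,
  weighted group means, exact percent differences, and a nine-trait report
  panel (`asat_anova()`, `monthly_contrasts()`, `trait_lrt()`,
  `weighted_group_mean()`, `percent_change()`, `table2_report()`).
* **Synthetic data with known truth** for every stage
  (`simulate_light_curve()`, `simulate_aci_curve()`, `simulate_season()`,
  `simulate_trait_table()`), plus CSV readers with configurable column
  dialects and row-level validation (`read_gas_exchange_log()`,
  `group_into_curves()`).

## Worked example

Simulate a light-response curve at known parameters and refit it:

```r
library(exclophys)
truth <- list(a_max = 9.40, phi = 0.077, r_d = 0.52, theta = 0.9)
curve <- simulate_light_curve(truth, noise_sd = 0.2, seed = 42)
fit_light_response(curve)
#> Non-rectangular hyperbola light-response fit
#>       estimate     se
#> a_max  9.41900 0.2140
#> phi    0.07479 0.0059
#> r_d    0.37350 0.1680
#> theta  0.89930 0.0343
#>   LCP = 5.02  LSP = 216.1 umol m-2 s-1   RSS = 0.249 (n = 11)
```

With instrument noise of 0.2 µmol m⁻² s⁻¹ on 11 points, the asymptote and
quantum yield come back within one standard error of truth; respiration is
the least certain parameter, as its information comes from the lowest light
steps only. A full simulated season, analysed the same way the field data
would be:

```r
sim <- simulate_season(season_scenario(seed = 42))
closure_day(fit_canopy_smooth(sim$sensor))
#> canopy closure: day 151 (decline began day 131)

fit <- fit_ppfd_lmm(sim$plants)
fit$term_table
#>             term    df likelihood_ratio        p signif
#> 1           Time (5,6)             5.52 1.88e-02      *
#> 2         Time^2 (6,7)             3.97 4.62e-02      *
#> 3        Fencing (7,8)            46.56 8.89e-12    ***
#> 4 Time x fencing (8,9)            15.24 9.45e-05    ***

treatment_means_original_scale(fit, 172)
#>   treatment day_of_year mean_ppfd    se
#> 1    fenced         172     17.58 3.747
#> 2  unfenced         172     63.96 4.911
```

The detected closure day (151) falls in the expected mid-May window, the
day × fencing interaction is strongly supported, and late-June fenced PPFD
is ~73 % below unfenced
(`percent_change(17.58, 63.96)$percent` = −72.5) — the fenced understory
darkens after canopy closure while the browsed side stays open.

## Layout

```
R/                 implementation
tests/testthat/    unit, property and acceptance tests (all seeded)
scripts/           acceptance script
vignettes/         methods vignette (models, assumptions, design choices)
```
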