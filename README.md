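# sylvacost

Carbon sequestration cost analysis for collectively owned forests.

Forests owned and managed collectively by farming households are a large
share of China's forest area, and the break-even carbon price on that
land — the price at which managing forest for timber and carbon matches
the agricultural profit the same plot would earn — is the minimum cost
of supplying forest carbon sequestration. sylvacost implements that cost
model and the analysis pipeline built around it, for researchers in
forest economics and ecological economics who want the methods as
tested, reusable, seedable code:

- **Equilibrium carbon price** over forest rotations. One rotation of
  length *U* earns `f = -c_a + p_w v (1+r)^{-U} + B`, with the carbon
  NPV `B = p_c (1-e) ω Σ_t (1+r)^{-t} − (1−θ)(1−e) p_c ω U (1+r)^{-U}`;
  annual uptake ω comes from a volume–biomass–NPP conversion of stand
  growth. Setting the perpetual-rotation value
  `F = f [1 − (1+r)^{-U}]^{-1}` equal to the agricultural opportunity
  cost *A* (Cobb–Douglas when computed from inputs) and solving for the
  carbon price gives the closed form in `equilibrium_carbon_price()`.
- **Distribution dynamics** of the cross-province cost by Gaussian
  kernel density estimation (`kde_evaluate()`, `density_by_group()`).
- **LSTM forecasting** of the national mean cost to 2030 — a 50-unit
  network trained 150 epochs with 5% dropout, implemented in plain R
  with fully seeded, bit-reproducible training (`fit_lstm()`,
  `forecast_recursive()`).
- **Spatial panel econometrics**: weight matrices from contiguity,
  geographic or economic distance (`build_weights()`), Anselin LM tests
  for spatial dependence (`lm_tests()`), QML estimation of the spatial
  Durbin model `y = ρWy + Xβ + WXθ + FE + ε` and its SAR/SEM/OLS limits
  (`fit_sdm()`), and direct/indirect/total effect decomposition with
  simulation-based t-values (`decompose_effects()`,
  `robustness_sweep()`).
- **A synthetic panel generator** with known ground truth
  (`generate_cost_inputs()`, `generate_sdm_panel()`) and a one-command
  pipeline (`run_pipeline()`), so the whole analysis runs end to end
  without any proprietary yearbook data.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, ggplot2 plot functions per result
type.

## Worked example

Price one representative hectare, then fit the spatial model on a
generated 29-province, 30-year panel with known coefficients:

```r
library(sylvacost)

omega <- npp_carbon_uptake(volume = 80, age = 20, biomass_coeff = 0.6,
                           biomass_exponent = 1.02, species_c = 0.5,
                           species_d = 0.02, root_stem_ratio = 0.25)
round(omega, 4)
#> [1] 1.2872          # tC/ha/yr of realised uptake

price <- equilibrium_carbon_price(
  opportunity_cost = 5800, afforestation_cost = 6000,
  timber_price = 400, timber_volume = 40,
  discount_rate = 0.03, rotation = 25, uptake = omega, basis = "tCO2e")
round(as.numeric(price), 2)
#> [1] 20.22           # CNY per tCO2e to break even with agriculture

w <- generate_adjacency(29, "random_planar", seed = 1)
W <- build_weights(w$W, kind = "contiguity")
truth <- sdm_ground_truth(rho = 0.3,
                          beta = c(tech = -0.8, social = 0.9, nature = -0.4),
                          theta = c(tech = 0.3, social = 0.4, nature = 0.2))
sim <- generate_sdm_panel(W, truth, generator_config(seed = 1))
fit <- fit_sdm(sim$panel, W, "lncc", c("tech", "social", "nature"),
               fixed_effects = "twoway")
fit
#> <sdm_fit> SDM, twoway fixed effects; n = 29, T = 30
#>   rho = 0.3358
#>   beta:
#>    tech  social  nature
#> -0.7429  0.8874 -0.4083
#>   theta (W x covariate):
#>   tech social nature
#> 0.3518 0.4110 0.1845
#>   sigma2 = 0.9713, logLik = -1140.63, pseudo-R2 = 0.698

decompose_effects(fit, W, seed = 1)
#> # A tibble: 3 x 7
#>   covariate direct indirect  total direct_t indirect_t total_t
#> 1 tech      -0.731   0.142  -0.589    -20.6      1.85    -6.82
#> 2 social     0.970   0.985   1.95      26.8     11.8     19.9
#> 3 nature    -0.403   0.0658 -0.337    -11.1      0.849   -3.65
```

The fit recovers the generating coefficients (ρ = 0.3, β, θ) within
sampling error; the effects table splits each covariate's impact into
the own-province (direct) part, the spillover to and from neighbours
(indirect), and their sum, with t-values from 2,000 seeded draws of the
coefficient distribution. `total` always equals `direct + indirect`.

For the full pipeline — simulate, price the panel, estimate yearly
density curves, forecast, fit the SDM, decompose and sweep alternative
weight matrices:

```r
cfg <- pipeline_config(out_dir = "run", seed = 1)
manifest <- run_pipeline(cfg)
report_summary(manifest)
```

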