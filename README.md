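# fluvialghg

Analysis of paired pCO₂ / dissolved-CH₄ measurements in tropical river
networks, and regression-based upscaling of river and stream CO₂ evasion to a
tropics-wide total with Monte Carlo error propagation.

## Who it is for

Aquatic biogeochemists working with concurrent measurements of the partial
pressure of CO₂ (pCO₂, ppm) and dissolved CH₄ (nmol L⁻¹) in river channels,
who want to (i) stratify and compare those measurements across channel
classes and basins, (ii) relate basin-level median pCO₂ to catchment wetland
coverage, and (iii) extrapolate the relation over a COSCAT-structured global
river GIS table to an area-integrated CO₂ flux with an honest uncertainty.

## The model

Areal air–water exchange follows

```
F = k · α · (pCO₂_water − pCO₂_air)        [mmol m⁻² d⁻¹]
```

with gas transfer velocity *k* (m d⁻¹), Weiss-form CO₂ solubility *α*
(mol L⁻¹ atm⁻¹, evaluated at 25 °C for the upscaling) and the gradient
against a 390 ppm atmosphere; positive *F* is evasion. Water pCO₂ per
catchment unit is predicted from per-class ordinary least squares of basin
median pCO₂ on the catchment wetland coverage fraction:
small streams (<100 m) from the `T<100m` line, wide channels from the mean of
the `MS` and `T>100m` lines. Per-unit fluxes are scaled by the river/stream
surface areas and summed over 30°N–30°S. Uncertainty in the regression
coefficients (bivariate-normal draws with the fitted covariance), in *k*
(±10 % relative SD) and in the surface areas (±31 %) is propagated by a
1000-iteration Monte Carlo.

Dissolved CH₄ is recovered from vial headspace equilibrations by a two-phase
mass balance (ideal-gas headspace + residual dissolved CH₄ via the CH₄
solubility at the equilibration temperature). Channel classes are compared
with tie-corrected Kruskal–Wallis and Mann–Whitney tests, and the CH₄–pCO₂
coupling per stratum with OLS of log₁₀(CH₄) on pCO₂.

Synthetic-data generators (`generate_measurements()`, `generate_coscat()`)
produce measurement sets and upscaling tables with known ground truth, so the
whole pipeline is testable end to end without external data.

## Worked example

```r
library(fluvialghg)

# 1. stratified measurements (two-basin synthetic preset: 136 + 280 records)
meas <- generate_measurements(two_basin_config(), seed = 1)
summarize_measurements(meas)[, c("river", "channel_class", "n",
                                 "pco2_median", "ch4_median")]
#>    river channel_class   n pco2_median ch4_median
#> 1 Amazon            MS  60        4532      79.24
#> 2 Amazon        T<100m  36        7204     379.38
#> 3 Amazon        T>100m  40        4851     156.14
#> 4  Congo            MS 120        2765     340.30
#> 5  Congo        T<100m  80        6588    1213.94
#> 6  Congo        T>100m  80        4355     512.97

compare_rivers(meas, "ch4")
#>   channel_class median_Amazon median_Congo   U  p_value higher
#> 1            MS          79.2          340 471 2.24e-21  Congo
#> 2        T>100m         156.1          513 526 2.28e-09  Congo
#> 3        T<100m         379.4         1214 834 3.02e-04  Congo

# 2. wetland regressions over synthetic basins with known true lines
truths <- generate_coscat(coscat_sim_config(n_cells = 60), seed = 1)
wf  <- c(a = 0.01, b = 0.04, c = 0.08, d = 0.12, e = 0.18, f = 0.25, g = 0.32)
pts <- generate_basin_points(truths$true_models, wf, noise_sd = 350, seed = 2)
models <- fit_wetland_regressions(pts)
models[["T<100m"]]
#> median pCO2 ~ wetland fraction [T<100m]:
#>   slope     26815.8 +/- 1837.8 ppm per unit fraction
#>   intercept 3436.7 +/- 325.7 ppm
#>   r2 = 0.977 over 7 basins

# 3. upscale and 4. propagate
tropical_total(truths$cells, models)$total_pgc_yr
#> [1] 0.2544241
mc <- mc_propagate(truths$cells, models, config = mc_config(seed = 3))
summarize_mc(mc)
#> [1] "0.3 ± 0.1 PgC yr-1 (2.5-97.5%: 0.1-0.4)"
truths$true_total_pgc_yr   # known ground truth, inside the interval
#> [1] 0.2495691
```

The summary table shows per-stratum medians: pCO₂ rises from the mainstem to
the small tributaries in both basins, and CH₄ is higher in the Congo-like
basin in every class (all Mann–Whitney p < 0.05) — the configured pattern,
recovered by the tests. The upscaling block shows the fitted small-stream
line recovering its generating slope/intercept within errors, and the Monte
Carlo interval covering the analytically known true total.

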