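---
title: "From paired pCO2/CH4 measurements to a tropical river CO2 evasion estimate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From paired pCO2/CH4 measurements to a tropical river CO2 evasion estimate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluvialghg)
```

## The problem

Rivers and streams of the lowland tropics are strongly supersaturated in CO2
relative to the atmosphere (~390 ppm) and evade it at globally significant
rates. `fluvialghg` implements an analysis pipeline for paired measurements of
water pCO2 (ppm) and dissolved CH4 (nmol L^-1^) across river networks, and a
regression-based extrapolation of those measurements to a tropics-wide CO2
evasion estimate with Monte Carlo error propagation.

The pipeline has four stages:

1. **Measurements** — read, validate and stratify paired pCO2/CH4 records by
   basin and channel class (mainstem `MS`, large tributaries `T>100m`, small
   tributaries `T<100m`), summarise each stratum, and compare strata with
   rank-based tests (Kruskal-Wallis across classes, Mann-Whitney between
   basins). The coupling of the two gases is characterised by ordinary least
   squares of log10(CH4) on untransformed pCO2 per stratum.
2. **Wetland model** — regress the per-basin, per-class *median* pCO2 on the
   catchment wetland coverage fraction across basins, one line per channel
   class, keeping coefficient standard errors and their covariance.
3. **Upscaling** — evaluate those regressions at the wetland fraction of each
   catchment unit (COSCAT) of a global river GIS table, convert the predicted
   pCO2 to an areal flux `F = k * alpha * (pCO2_water - pCO2_air)`, scale by
   the river/stream surface area of each unit, and sum over the 30°N-30°S
   band.
4. **Uncertainty** — propagate the regression-coefficient, gas-transfer and
   surface-area uncertainties by Monte Carlo.

## Physical chemistry

The CO2 solubility coefficient uses the Weiss-form polynomial
`ln(alpha) = A1 + A2 (100/T) + A3 ln(T/100) + S (B1 + B2 (T/100) + B3 (T/100)^2)`
with T in kelvin, giving alpha in mol L^-1^ atm^-1^ (0.0340 at 25 °C,
freshwater). The flux arithmetic exploits the unit identity
1 mol L^-1^ atm^-1^ = 1 mmol m^-3^ uatm^-1^, so with k in m d^-1^ and the
gradient in uatm the product `k * alpha * dpCO2` is directly in
mmol m^-2^ d^-1^. pCO2 in ppm is treated as uatm at 1 atm total pressure; the
difference is below the ~2 % precision of field pCO2 measurements. No Schmidt
number conversion is applied to k: at the fixed 25 °C, Sc(CO2) is close to
600, so the tabulated k values are used as-is.

Dissolved CH4 is recovered from a vial headspace equilibration by a two-phase
mass balance: after equilibration the measured headspace mixing ratio `x`
fixes both the gas-phase amount (ideal gas, `x P V_g / (R T)`) and the amount
still dissolved (`x P beta(T) V_w`, with beta the CH4 solubility at the
equilibration temperature, from the standard freshwater Bunsen-coefficient
fit divided by 22.414 L mol^-1^); the original concentration is their sum per
litre of water. The laboratory equilibration temperature and pressure are
protocol-dependent and are therefore explicit arguments (defaults 25 °C,
1 atm), not hidden constants. `dissolved_ch4_to_headspace()` inverts the
balance, and the round trip recovers inputs to 1e-10 relative tolerance.

## Statistical choices

* Percentiles use the type-7 (linear interpolation) definition throughout.
* A channel exactly 100 m wide is classed `T>100m`; the class boundaries are
  otherwise strict, and the mainstem flag dominates width.
* Rank tests are two-sided with tie correction; the Mann-Whitney p-value is
  exact (permutation distribution) for small untied samples and the
  tie-corrected normal approximation otherwise; significance is read at 0.05.
  A Kruskal-Wallis call on fully tied data returns H = 0, p = 1 — the limit
  of "no evidence against equality" — rather than the 0/0 of the raw
  tie-correction formula.
* Basin-wide concentration ranges pool all channel classes of a basin.
* The wetland regressions are *unweighted* OLS across basins: basins
  contribute equally even though their record counts differ by an order of
  magnitude, because each point is a basin-level median, not a sample mean
  with a standard error.
* Wetland coverage is a fraction in [0, 1]; tables in percent are converted
  when flagged.
* Predicted pCO2 is floored at 0 ppm. Sub-atmospheric (but positive)
  predictions are legitimate and produce invasion (negative) fluxes; negative
  partial pressures are not.

## Upscaling rules

The COSCAT table carries two pre-aggregated size classes per unit (narrower
and wider than 100 m) because stream-order-structured GIS areas cannot be
split into mainstem versus tributaries. The small-class pCO2 comes from the
`T<100m` regression; the large-class pCO2 is the arithmetic mean of the `MS`
and `T>100m` regression predictions. The tropical band is inclusive at ±30°
latitude, and excluded cells are counted rather than silently dropped. The
25 °C solubility temperature and 390 ppm atmospheric pCO2 live in
`gas_constants()` so sensitivity runs can change them. Area integration uses
365.25 d yr^-1^ and 12.011 g C mol^-1^, reporting Pg C yr^-1^.

## Monte Carlo error propagation

Three uncertainty sources are propagated, with defaults matching the upstream
data products: regression coefficients (from the fitted standard errors and
covariance), gas transfer velocities (±10 % relative SD) and river/stream
surface areas (±31 % relative SD, the spread between the two hydraulic
equations used to build such areas). Per iteration, each class model's
(intercept, slope) pair is drawn from the fitted bivariate normal — jointly
by default, since the two estimates are strongly negatively correlated;
independent sampling is available for sensitivity (`use_coef_covariance =
FALSE`), and a non-positive-definite covariance falls back to it with a
warning. Coefficient draws are shared by all cells within an iteration: the
regression is one model, not per-cell noise.

"±10 %" statements are ambiguous between a 1-SD normal error and a uniform
half-range; the default is a zero-truncated normal multiplicative
perturbation, with `dist = "uniform"` covering the other reading. The k and
area perturbations default to one global draw per iteration
(`error_correlation = "global"`): systematic choices in the source GIS (which
hydraulic equation, which k parameterisation) shift all cells together, and
the global mode yields the larger, more conservative uncertainty. Per-cell
independent draws are available and demonstrably narrower. The k perturbation
is shared by the two size classes of a cell for the same reason. The number
of iterations defaults to 1000; everything derives from one integer seed, and
identical seeds give bit-identical results.

The reported central value is the ensemble mean, with the deterministic
(zero-noise) total carried alongside; in the small-relative-error regime they
agree closely because the flux is linear in every perturbed quantity.

## What the synthetic generator emulates — and what it does not

`generate_measurements()` draws pCO2 per stratum from a log-normal with a
configured median and geometric SD (field pCO2 and CH4 are right-skewed, with
medians far below means and ranges spanning orders of magnitude) and couples
log10(CH4) to pCO2 through a configurable affine relation with Gaussian
noise. The `two_basin_config()` preset fixes the study conditions used by the
tests: 136 records in an "Amazon-like" basin (wetland coverage 0.14) and 280
in a "Congo-like" basin (0.10), class-ordered pCO2 medians
(MS < T>100m < T<100m), a higher mainstem pCO2 in basin A and a higher CH4
intercept (more CH4 at a given pCO2) in basin B, including a weak *negative*
mainstem coupling in basin A. Those are shapes and sample sizes, not
measured values.

`generate_coscat()` draws catchment units with Beta(1.2, 8) wetland fractions
(right-skewed, mostly below ~25 %), log-normal k (median 2.5 m d^-1^) and
areas, and returns the analytically exact tropical total implied by the
configured true regression lines, enabling end-to-end recovery tests: fit the
regressions on noisy synthetic basin medians, upscale, propagate, and check
the true total falls in the Monte Carlo 95 % interval in at least 90 % of
replicate worlds.

The generator does **not** emulate spatial autocorrelation along a cruise
track, seasonality of the flood pulse, measurement error structure, or any
mechanistic link between wetland extent and CH4 production. Passing tests
therefore demonstrate that the pipeline's arithmetic, fitting and propagation
are correct under the stated distributional assumptions — not that those
assumptions hold in any particular basin.

## Problem sizes and numerical details

The test-suite and acceptance runs use 60-cell COSCAT tables, 7 synthetic
basins, 1000-iteration Monte Carlo ensembles (10^5 where a tight check on an
ensemble SD is needed) and 50 replicate worlds for the coverage property —
sizes at which every stochastic tolerance in the tests has comfortable
headroom. Truncation at zero of the multiplicative perturbations is by
redraw, which at relative SDs up to 0.31 biases the mean by well under 1 %.
Degenerate inputs fail loudly: empty strata, fewer than 3 regression points,
zero predictor variance, non-positive volumes and out-of-range latitudes or
fractions are all errors, not silent NA propagation.

## Worked example

```{r example}
## 1. stratified measurements and between-class statistics
meas <- generate_measurements(two_basin_config(), seed = 1)
summarize_measurements(meas)[, c("river", "channel_class", "n", "pco2_median", "ch4_median")]
kruskal_wallis(meas$pco2[meas$river == "Congo"],
               meas$channel_class[meas$river == "Congo"])$p_value
compare_rivers(meas, "ch4")

## 2. wetland regressions across basins (needs >= 3 basins; use the
##    synthetic multi-basin generator)
truths <- generate_coscat(coscat_sim_config(n_cells = 60), seed = 1)
wf <- c(a = 0.01, b = 0.04, c = 0.08, d = 0.12, e = 0.18, f = 0.25, g = 0.32)
pts <- generate_basin_points(truths$true_models, wf, noise_sd = 350, seed = 2)
models <- fit_wetland_regressions(pts)
models[["T<100m"]]

## 3. deterministic upscaling and 4. Monte Carlo propagation
det <- tropical_total(truths$cells, models)
det$total_pgc_yr
mc <- mc_propagate(truths$cells, models, config = mc_config(seed = 3))
summarize_mc(mc)
truths$true_total_pgc_yr   # known ground truth, inside the interval
```

## Known limitations

* The wetland model is a straight line per channel class; no additional
  predictors (temperature, runoff, stream order) and no nonlinearity.
* k is consumed as an input column of the upscaling table; the package does
  not derive it from slope and velocity.
* No ebullition: CH4 is analysed as dissolved concentration only, and the
  upscaled flux concerns CO2.
* Uncertainty is propagated for regression coefficients, k and areas only;
  water temperature, atmospheric pCO2 and wetland fractions are treated as
  exact.
* A tropics-wide total computed from synthetic COSCAT tables validates the
  machinery; a real-world estimate requires the external global river GIS and
  wetland database, which are not bundled.
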