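Package: fluvialghg
Title: Paired CO2/CH4 River Measurements and Upscaling of Tropical River CO2 Evasion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing paired measurements of the partial pressure of
    CO2 (pCO2) and dissolved CH4 in tropical river networks, and for upscaling
    river and stream CO2 evasion over catchment units. Includes a
    physical-chemistry core (Weiss-form CO2 solubility, air-water gas exchange
    flux, headspace-equilibration back-calculation of dissolved CH4),
    stratified nonparametric comparisons across channel classes, per-class
    linear regressions of median pCO2 on catchment wetland coverage,
    regression-based prediction of pCO2 over COSCAT-style upscaling tables,
    Monte Carlo propagation of regression, gas-transfer-velocity and
    surface-area uncertainties to the tropical total flux, and synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
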