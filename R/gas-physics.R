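# Physical-chemistry core: CO2 solubility, air-water gas exchange flux,
# headspace-equilibration back-calculation of dissolved CH4, unit conversions.

# Ideal gas constant in L atm mol-1 K-1 (CODATA-derived).
.R_L_ATM <- 0.0820573660809596

#' Gas-exchange constants
#'
#' Bundle of the constants used throughout the flux computations: the water
#' temperature at which the CO2 solubility coefficient is evaluated, the
#' atmospheric pCO2 against which the air-water gradient is formed, and the
#' salinity (zero for freshwater). pCO2 in ppm is treated as uatm assuming
#' 1 atm total pressure; the difference is below the ~2 % measurement
#' precision of field pCO2. The atmospheric CH4 equilibrium concentration
#' (~2 nmol/L) is carried for reporting only; it does not enter the CO2 flux
#' arithmetic.
#'
#' @param water_temp Water temperature in degrees Celsius, in \[0, 40\].
#'   Default 25.
#' @param atm_pco2 Atmospheric pCO2 in ppm (treated as uatm). Default 390.
#' @param salinity Salinity in per mil. Default 0 (freshwater).
#' @param atm_ch4_nmol Atmospheric-equilibrium dissolved CH4 in nmol/L,
#'   reported alongside results but not used in flux computations. Default 2.
#' @return An object of class `gas_constants` (a list with the four fields).
#' @examples
#' gas_constants()
#' gas_constants(water_temp = 28)
#' @export
gas_constants <- function(water_temp = 25, atm_pco2 = 390, salinity = 0,
                          atm_ch4_nmol = 2) {
  stopifnot(is.numeric(water_temp), length(water_temp) == 1L,
            is.numeric(atm_pco2), length(atm_pco2) == 1L,
            is.numeric(salinity), length(salinity) == 1L)
  if (water_temp < 0 || water_temp > 40)
    stop("water_temp must be within [0, 40] degrees C, got ", water_temp)
  if (atm_pco2 <= 0) stop("atm_pco2 must be > 0")
  if (salinity < 0) stop("salinity must be >= 0")
  structure(list(water_temp = water_temp, atm_pco2 = atm_pco2,
                 salinity = salinity, atm_ch4_nmol = atm_ch4_nmol),
            class = "gas_constants")
}

#' @export
print.gas_constants <- function(x, ...) {
  cat("Gas-exchange constants:\n",
      "  water temperature : ", x$water_temp, " degC\n",
      "  atmospheric pCO2  : ", x$atm_pco2, " ppm\n",
      "  salinity          : ", x$salinity, " per mil\n",
      "  atm. equil. CH4   : ", x$atm_ch4_nmol, " nmol/L\n", sep = "")
  invisible(x)
}

#' CO2 solubility coefficient (Weiss form)
#'
#' Solubility of CO2 in water as a function of temperature and salinity,
#' using the Weiss-form polynomial in mol L-1 atm-1:
#' `ln(alpha) = A1 + A2*(100/T) + A3*ln(T/100) + S*(B1 + B2*(T/100) + B3*(T/100)^2)`
#' with T in kelvin and S in per mil. Solubility decreases strictly with
#' temperature over the environmental range.
#'
#' @param temp Water temperature in degrees Celsius, in \[-1, 45\].
#' @param salinity Salinity in per mil (>= 0). Default 0 (freshwater).
#' @return Solubility coefficient alpha in mol L-1 atm-1. Vectorised over
#'   `temp`.
#' @examples
#' co2_solubility(25)   # ~0.0340 mol L-1 atm-1
#' co2_solubility(0)    # ~0.0776 mol L-1 atm-1
#' @export
co2_solubility <- function(temp, salinity = 0) {
  if (any(!is.finite(temp)) || any(temp < -1) || any(temp > 45))
    stop("temp out of range: valid range is [-1, 45] degrees C")
  if (any(salinity < 0)) stop("salinity must be >= 0")
  tk <- (temp + 273.15) / 100
  exp(-58.0931 + 90.5069 / tk + 22.2940 * log(tk) +
        salinity * (0.027766 - 0.025888 * tk + 0.0050578 * tk^2))
}

#' CH4 solubility coefficient
#'
#' Henry-type solubility of CH4 in water in mol L-1 atm-1, from the standard
#' freshwater/seawater Bunsen-coefficient fit (same functional form as the
#' CO2 polynomial, coefficients for CH4), divided by the STP molar volume
#' 22.414 L mol-1. Used in the headspace two-phase mass balance.
#'
#' @inheritParams co2_solubility
#' @return Solubility in mol L-1 atm-1. Vectorised over `temp`.
#' @examples
#' ch4_solubility(25)  # ~1.41e-3 mol L-1 atm-1
#' @export
ch4_solubility <- function(temp, salinity = 0) {
  if (any(!is.finite(temp)) || any(temp < -1) || any(temp > 45))
    stop("temp out of range: valid range is [-1, 45] degrees C")
  if (any(salinity < 0)) stop("salinity must be >= 0")
  tk <- (temp + 273.15) / 100
  bunsen <- exp(-67.1962 + 99.1624 / tk + 27.9015 * log(tk) +
                  salinity * (-0.072909 + 0.041674 * tk - 0.0064603 * tk^2))
  bunsen / 22.414
}

#' Air-water CO2 flux
#'
#' Areal air-water CO2 exchange flux `F = k * alpha * (pCO2_water - pCO2_air)`.
#' A positive value is an evasion of CO2 from the water to the atmosphere;
#' a negative value an invasion. With alpha in mol L-1 atm-1, k in m d-1 and
#' the gradient in uatm, the product is numerically in mmol m-2 d-1
#' (1 mol L-1 atm-1 = 1 mmol m-3 uatm-1).
#'
#' @param alpha CO2 solubility coefficient in mol L-1 atm-1 (> 0).
#' @param k Gas transfer velocity in m d-1 (>= 0).
#' @param pco2_water Water pCO2 in uatm (ppm at 1 atm).
#' @param pco2_air Atmospheric pCO2 in uatm. Default 390.
#' @return Areal flux in mmol CO2 m-2 d-1. Vectorised.
#' @examples
#' co2_flux(co2_solubility(25), k = 1, pco2_water = 1390, pco2_air = 390)
#' @export
co2_flux <- function(alpha, k, pco2_water, pco2_air = 390) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (any(k < 0)) stop("k must be >= 0 (negative gas transfer velocity)")
  k * alpha * (pco2_water - pco2_air)
}

#' Scale an areal flux to an area-integrated flux
#'
#' Converts an areal flux in mmol CO2 m-2 d-1 over a surface area in km2 to
#' an annual carbon flux in Pg C yr-1, using 365.25 d yr-1 and
#' 12.011 g C mol-1.
#'
#' @param F Areal flux in mmol m-2 d-1.
#' @param area Surface area in km2 (>= 0).
#' @return Integrated flux in Pg C yr-1. Vectorised.
#' @examples
#' areal_to_integrated(34, 1)  # ~1.49e-7 PgC/yr
#' @export
areal_to_integrated <- function(F, area) {
  if (any(area < 0)) stop("area must be >= 0")
  # mmol -> mol (1e-3), km2 -> m2 (1e6), g -> Pg (1e-15)
  F * 1e-3 * area * 1e6 * 365.25 * 12.011 * 1e-15
}

#' Headspace-equilibration setup
#'
#' Describes a serum-vial headspace equilibration for dissolved CH4: a vial
#' of `vial_volume` mL initially full of sample water, in which a
#' `headspace_volume` mL headspace of N2 is created (displacing water), shaken
#' and left to equilibrate at `equilibration_temp`; the CH4 mixing ratio of
#' the headspace is then measured by gas chromatography.
#'
#' @param measured_mixing_ratio Measured headspace CH4 mixing ratio in ppm
#'   (>= 0).
#' @param vial_volume Vial volume in mL. Default 50.
#' @param headspace_volume Headspace (N2) volume in mL. Default 20.
#' @param water_volume Water volume in mL; defaults to
#'   `vial_volume - headspace_volume`.
#' @param equilibration_temp Laboratory equilibration temperature in degrees
#'   Celsius. Default 25; configurable because it is protocol-dependent.
#' @param lab_pressure Laboratory pressure in atm. Default 1.
#' @return An object of class `headspace_setup`.
#' @examples
#' headspace_setup(measured_mixing_ratio = 10)
#' @export
headspace_setup <- function(measured_mixing_ratio,
                            vial_volume = 50,
                            headspace_volume = 20,
                            water_volume = vial_volume - headspace_volume,
                            equilibration_temp = 25,
                            lab_pressure = 1) {
  stopifnot(is.numeric(measured_mixing_ratio))
  if (any(measured_mixing_ratio < 0))
    stop("measured_mixing_ratio must be >= 0")
  if (vial_volume <= 0 || headspace_volume <= 0 || water_volume <= 0)
    stop("all volumes must be > 0")
  if (headspace_volume + water_volume > vial_volume + 1e-9)
    stop("headspace_volume + water_volume exceeds vial_volume")
  if (lab_pressure <= 0) stop("lab_pressure must be > 0")
  structure(list(measured_mixing_ratio = measured_mixing_ratio,
                 vial_volume = vial_volume,
                 headspace_volume = headspace_volume,
                 water_volume = water_volume,
                 equilibration_temp = equilibration_temp,
                 lab_pressure = lab_pressure),
            class = "headspace_setup")
}

#' Dissolved CH4 from a headspace equilibration
#'
#' Back-calculates the original dissolved CH4 concentration from the measured
#' headspace mixing ratio by a two-phase mass balance at equilibrium: the
#' total CH4 in the vial is the gas-phase amount (ideal gas,
#' `x * P * V_g / (R * T)`) plus the amount still dissolved
#' (`x * P * beta(T) * V_w`, with beta the CH4 solubility at the
#' equilibration temperature), and the original concentration is that total
#' divided by the water volume. Linear in the measured mixing ratio.
#'
#' @param setup A [headspace_setup()] object.
#' @return Original dissolved CH4 concentration in nmol L-1 (vector if the
#'   setup carries several mixing ratios).
#' @examples
#' headspace_to_dissolved_ch4(headspace_setup(10))
#' @export
headspace_to_dissolved_ch4 <- function(setup) {
  stopifnot(inherits(setup, "headspace_setup"))
  if (setup$water_volume <= 0) stop("water volume must be > 0")
  x <- setup$measured_mixing_ratio * 1e-6      # atm/atm
  p <- setup$lab_pressure                      # atm
  vg <- setup$headspace_volume / 1000          # L
  vw <- setup$water_volume / 1000              # L
  tk <- setup$equilibration_temp + 273.15
  beta <- ch4_solubility(setup$equilibration_temp)
  n_gas <- x * p * vg / (.R_L_ATM * tk)        # mol
  n_dis <- x * p * beta * vw                   # mol
  (n_gas + n_dis) / vw * 1e9                   # nmol/L
}

#' Equilibrium headspace mixing ratio implied by a dissolved concentration
#'
#' Inverse of [headspace_to_dissolved_ch4()]: given an original dissolved CH4
#' concentration, returns the headspace mixing ratio that the same two-phase
#' mass balance predicts after equilibration. Used for round-trip validation.
#'
#' @param conc_nmol_l Original dissolved CH4 concentration in nmol L-1.
#' @param setup A [headspace_setup()] object (its `measured_mixing_ratio` is
#'   ignored).
#' @return Equilibrium headspace mixing ratio in ppm.
#' @export
dissolved_ch4_to_headspace <- function(conc_nmol_l, setup) {
  stopifnot(inherits(setup, "headspace_setup"))
  p <- setup$lab_pressure
  vg <- setup$headspace_volume / 1000
  vw <- setup$water_volume / 1000
  tk <- setup$equilibration_temp + 273.15
  beta <- ch4_solubility(setup$equilibration_temp)
  n_total <- conc_nmol_l * 1e-9 * vw
  n_total / (p * (vg / (.R_L_ATM * tk) + beta * vw)) * 1e6
}

#' Specific discharge of a river basin
#'
#' Annual discharge divided by catchment area, in the conventional
#' L s-1 km-2.
#'
#' @param discharge_km3_yr Freshwater discharge in km3 yr-1.
#' @param catchment_area_km2 Catchment area in km2 (> 0).
#' @return Specific discharge in L s-1 km-2.
#' @examples
#' specific_discharge(5444, 6025735)  # ~29
#' @export
specific_discharge <- function(discharge_km3_yr, catchment_area_km2) {
  if (any(catchment_area_km2 <= 0)) stop("catchment area must be > 0")
  discharge_km3_yr * 1e12 / (365.25 * 86400) / catchment_area_km2
}
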