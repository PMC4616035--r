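# Application of the fitted wetland regressions over a COSCAT-structured
# table: per-unit and tropics-total river/stream CO2 evasion.

.coscat_cols <- c("coscat_id", "latitude", "wetland_fraction", "k_small_m_d",
                  "k_large_m_d", "area_small_km2", "area_large_km2")

#' Read a COSCAT upscaling table
#'
#' One row per catchment unit with, per stream-size class (narrower/wider
#' than 100 m), a gas transfer velocity and a river/stream surface area, plus
#' the unit's wetland coverage fraction and representative latitude.
#' Columns: `coscat_id, latitude, wetland_fraction, k_small_m_d, k_large_m_d,
#' area_small_km2, area_large_km2`.
#'
#' @param path Path to a CSV file.
#' @return A validated data.frame of COSCAT cells.
#' @export
read_coscat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.coscat_cols, names(d))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  validate_coscat(d)
  d
}

#' Validate a COSCAT table against its invariants
#'
#' @param cells A COSCAT data.frame.
#' @return `cells`, invisibly; stops on the first violated invariant.
#' @export
validate_coscat <- function(cells) {
  missing <- setdiff(.coscat_cols, names(cells))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (any(cells$latitude < -90 | cells$latitude > 90))
    stop("latitude must lie in [-90, 90]")
  if (any(cells$wetland_fraction < 0 | cells$wetland_fraction > 1))
    stop("wetland_fraction must lie in [0, 1]")
  if (any(cells$k_small_m_d < 0 | cells$k_large_m_d < 0))
    stop("gas transfer velocities must be >= 0")
  if (any(cells$area_small_km2 < 0 | cells$area_large_km2 < 0))
    stop("surface areas must be >= 0")
  invisible(cells)
}

#' Predict per-cell pCO2 for the two size classes
#'
#' The small-stream pCO2 comes from the `T<100m` regression evaluated at the
#' cell's wetland fraction. Because the upscaling table cannot separate
#' mainstem from large-tributary surface area, the large-channel pCO2 is the
#' arithmetic mean of the `MS` and `T>100m` regression predictions.
#'
#' @param models Named list of the three `wetland_regression` objects
#'   (`MS`, `T>100m`, `T<100m`).
#' @param wetland_fraction Wetland fraction(s) of the cell(s).
#' @return A list with numeric vectors `pco2_small` and `pco2_msT` (ppm).
#' @export
predict_cell_pco2 <- function(models, wetland_fraction) {
  stopifnot(all(CHANNEL_CLASSES %in% names(models)))
  p_small <- predict_pco2(models[["T<100m"]], wetland_fraction)
  p_ms <- predict_pco2(models[["MS"]], wetland_fraction)
  p_t100 <- predict_pco2(models[["T>100m"]], wetland_fraction)
  list(pco2_small = p_small, pco2_msT = (p_ms + p_t100) / 2)
}

#' Per-cell CO2 evasion
#'
#' Computes, for each COSCAT cell, the areal CO2 flux of each size class
#' (solubility at the configured water temperature, gradient against the
#' configured atmospheric pCO2) and the cell's area-integrated total.
#'
#' @param cells A COSCAT data.frame (see [read_coscat()]).
#' @param pco2_small,pco2_msT Predicted water pCO2 (ppm) for the small and
#'   large size classes, recycled along the cells.
#' @param constants A [gas_constants()] object.
#' @return `cells` with added columns `pco2_small, pco2_msT, F_small,
#'   F_large` (mmol m-2 d-1) and `total_pgc_yr` (Pg C yr-1).
#' @export
cell_flux <- function(cells, pco2_small, pco2_msT, constants = gas_constants()) {
  validate_coscat(cells)
  stopifnot(inherits(constants, "gas_constants"))
  alpha <- co2_solubility(constants$water_temp, constants$salinity)
  f_small <- co2_flux(alpha, cells$k_small_m_d, pco2_small, constants$atm_pco2)
  f_large <- co2_flux(alpha, cells$k_large_m_d, pco2_msT, constants$atm_pco2)
  cells$pco2_small <- pco2_small
  cells$pco2_msT <- pco2_msT
  cells$F_small <- f_small
  cells$F_large <- f_large
  cells$total_pgc_yr <- areal_to_integrated(f_small, cells$area_small_km2) +
    areal_to_integrated(f_large, cells$area_large_km2)
  cells
}

#' Tropical total CO2 evasion
#'
#' Predicts per-cell pCO2 from the wetland regressions, computes per-cell
#' fluxes and sums the area-integrated totals over the cells whose
#' representative latitude falls inside the tropical band (inclusive bounds).
#' Cells outside the band are excluded and counted.
#'
#' @param cells A COSCAT data.frame.
#' @param models Named list of the three `wetland_regression` objects.
#' @param constants A [gas_constants()] object.
#' @param lat_band Inclusive latitude band in degrees; default `c(-30, 30)`.
#' @return A list with `total_pgc_yr`, `n_cells_in_band`,
#'   `n_cells_excluded`, and the per-cell table `cells` (band cells only,
#'   with flux columns).
#' @export
tropical_total <- function(cells, models, constants = gas_constants(),
                           lat_band = c(-30, 30)) {
  validate_coscat(cells)
  if (nrow(cells) == 0L) stop("need at least one COSCAT cell")
  in_band <- cells$latitude >= lat_band[1] & cells$latitude <= lat_band[2]
  n_out <- sum(!in_band)
  if (!any(in_band)) {
    warning("no cells inside the latitude band [", lat_band[1], ", ",
            lat_band[2], "]; total is 0")
    return(list(total_pgc_yr = 0, n_cells_in_band = 0L,
                n_cells_excluded = n_out, cells = cells[in_band, , drop = FALSE]))
  }
  band <- cells[in_band, , drop = FALSE]
  p <- predict_cell_pco2(models, band$wetland_fraction)
  band <- cell_flux(band, p$pco2_small, p$pco2_msT, constants)
  list(total_pgc_yr = sum(band$total_pgc_yr),
       n_cells_in_band = nrow(band), n_cells_excluded = n_out,
       cells = band)
}

#' Write per-cell fluxes plus a totals row
#'
#' @param flux_cells The `cells` element of a [tropical_total()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_fluxes <- function(flux_cells, path) {
  out <- flux_cells
  totals <- out[1L, , drop = FALSE]
  totals[1L, ] <- NA
  totals$coscat_id <- "TOTAL"
  num <- c("area_small_km2", "area_large_km2", "total_pgc_yr")
  totals[num] <- lapply(out[num], sum)
  utils::write.csv(rbind(out, totals), path, row.names = FALSE)
  invisible(path)
}
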