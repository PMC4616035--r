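# Synthetic measurement data-sets and COSCAT tables with known ground truth,
# so every pipeline stage is testable without external data.

#' Stratum configuration for the measurement generator
#'
#' One row per river x channel class: the number of records, the log-normal
#' pCO2 distribution (median and geometric SD), and the log-linear CH4
#' coupling `log10(CH4) = intercept + slope * pCO2 + N(0, noise_sd)`.
#'
#' @param river River name.
#' @param channel_class One of `MS`, `T>100m`, `T<100m`.
#' @param n Records to generate (>= 0).
#' @param median_pco2 Median pCO2 in ppm (> 0).
#' @param gsd_pco2 Geometric SD of pCO2 (> 1).
#' @param ch4_slope Coupling slope in log10(nmol/L) per ppm.
#' @param ch4_intercept Coupling intercept in log10(nmol/L).
#' @param ch4_log_noise_sd SD of the Gaussian noise on log10(CH4) (>= 0).
#' @return A one-row data.frame; rbind rows to build a full configuration.
#' @export
stratum_config <- function(river, channel_class, n, median_pco2, gsd_pco2,
                           ch4_slope, ch4_intercept, ch4_log_noise_sd) {
  if (n < 0) stop("n must be >= 0")
  if (median_pco2 <= 0) stop("median_pco2 must be > 0")
  if (gsd_pco2 <= 1) stop("gsd_pco2 must be > 1")
  if (ch4_log_noise_sd < 0) stop("ch4_log_noise_sd must be >= 0")
  if (!channel_class %in% CHANNEL_CLASSES)
    stop("unknown channel_class: ", channel_class)
  data.frame(river = river, channel_class = channel_class, n = as.integer(n),
             median_pco2 = median_pco2, gsd_pco2 = gsd_pco2,
             ch4_slope = ch4_slope, ch4_intercept = ch4_intercept,
             ch4_log_noise_sd = ch4_log_noise_sd)
}

#' Default two-basin measurement configuration
#'
#' A realistic two-basin preset mimicking the shape of lowland tropical
#' paired pCO2/CH4 data: right-skewed distributions spanning orders of
#' magnitude, class-ordered pCO2 medians (MS < T>100m < T<100m), basin A
#' ("Amazon-like", wetland coverage 0.14) with the higher mainstem pCO2, and
#' basin B ("Congo-like", wetland coverage 0.10) with higher CH4 at a given
#' pCO2 (larger coupling intercept). Shapes only; the numbers are generator
#' settings, not measured values.
#'
#' @return A stratum-configuration data.frame (6 rows) with attribute
#'   `wetland_table`.
#' @export
two_basin_config <- function() {
  cfg <- rbind(
    stratum_config("Amazon", "MS",     60, 4300, 1.5, -2e-5, 2.00, 0.30),
    stratum_config("Amazon", "T>100m", 40, 5200, 1.7,  8e-5, 1.75, 0.35),
    stratum_config("Amazon", "T<100m", 36, 7500, 1.9,  1.2e-4, 1.60, 0.35),
    stratum_config("Congo",  "MS",    120, 2800, 1.4,  5e-5, 2.45, 0.25),
    stratum_config("Congo",  "T>100m", 80, 4200, 1.6,  9e-5, 2.30, 0.30),
    stratum_config("Congo",  "T<100m", 80, 6800, 1.8,  1.1e-4, 2.20, 0.30))
  attr(cfg, "wetland_table") <- data.frame(
    basin = c("Amazon", "Congo"), wetland_fraction = c(0.14, 0.10))
  cfg
}

#' Generate synthetic paired measurements
#'
#' Draws, per stratum, pCO2 from a log-normal with the configured median and
#' geometric SD, and log10(CH4) from the configured affine coupling to pCO2
#' plus Gaussian noise. Coordinates are uniform in the bounding box and dates
#' uniform in the date range. Deterministic per seed. All generated records
#' satisfy the measurement invariants by construction.
#'
#' @param config A stratum-configuration data.frame (rows from
#'   [stratum_config()]).
#' @param seed Integer seed.
#' @param bbox Bounding box `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param date_range Two dates (coercible by `as.Date`).
#' @return A measurement data.frame with the same columns as
#'   [read_measurements()] output.
#' @export
generate_measurements <- function(config, seed = 1L,
                                  bbox = c(-61, 25, -5, 3),
                                  date_range = c("2007-01-30", "2015-05-06")) {
  needed <- c("river", "channel_class", "n", "median_pco2", "gsd_pco2",
              "ch4_slope", "ch4_intercept", "ch4_log_noise_sd")
  missing <- setdiff(needed, names(config))
  if (length(missing))
    stop("invalid config, missing column(s): ", paste(missing, collapse = ", "))
  if (any(config$n < 0) || any(config$median_pco2 <= 0) ||
      any(config$gsd_pco2 <= 1))
    stop("invalid config: n >= 0, median_pco2 > 0, gsd_pco2 > 1 required")
  set.seed(seed)
  dr <- as.Date(date_range)
  rows <- lapply(seq_len(nrow(config)), function(i) {
    s <- config[i, ]
    if (s$n == 0L) return(NULL)
    pco2 <- stats::rlnorm(s$n, meanlog = log(s$median_pco2),
                          sdlog = log(s$gsd_pco2))
    log_ch4 <- s$ch4_intercept + s$ch4_slope * pco2 +
      stats::rnorm(s$n, 0, s$ch4_log_noise_sd)
    data.frame(river = s$river,
               date = dr[1] + floor(stats::runif(s$n, 0, as.numeric(dr[2] - dr[1]) + 1)),
               longitude = stats::runif(s$n, bbox[1], bbox[2]),
               latitude = stats::runif(s$n, bbox[3], bbox[4]),
               channel_class = s$channel_class,
               pco2 = pco2, ch4 = 10^log_ch4,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(river = character(), date = as.Date(character()),
                      longitude = numeric(), latitude = numeric(),
                      channel_class = character(), pco2 = numeric(),
                      ch4 = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' COSCAT simulation configuration
#'
#' Settings for [generate_coscat()]: cells with latitudes uniform in a range,
#' Beta-distributed wetland fractions, and log-normal gas transfer velocities
#' and surface areas per size class, plus the "true" (intercept, slope) pairs
#' of the three wetland regressions used to define the ground-truth total.
#'
#' @param n_cells Number of COSCAT cells (>= 1). Default 60.
#' @param lat_range Latitude range, degrees. Default `c(-30, 30)`.
#' @param wetland_shape1,wetland_shape2 Beta parameters of the wetland
#'   fraction. Defaults 1.2 and 8 (right-skewed, most catchments below ~25 %).
#' @param k_meanlog,k_sdlog Log-normal parameters of k (m d-1), shared by the
#'   two size classes. Defaults log(2.5) and 0.4.
#' @param area_small_meanlog,area_large_meanlog,area_sdlog Log-normal
#'   parameters of the class surface areas (km2). Defaults log(600), log(900)
#'   and 0.8.
#' @param true_models Named list (`MS`, `T>100m`, `T<100m`) of
#'   `c(intercept, slope)` pairs in ppm; defaults give class-ordered pCO2
#'   rising with wetland coverage.
#' @return An object of class `coscat_sim_config`.
#' @export
coscat_sim_config <- function(n_cells = 60, lat_range = c(-30, 30),
                              wetland_shape1 = 1.2, wetland_shape2 = 8,
                              k_meanlog = log(2.5), k_sdlog = 0.4,
                              area_small_meanlog = log(600),
                              area_large_meanlog = log(900),
                              area_sdlog = 0.8,
                              true_models = list(
                                "MS" = c(intercept = 1500, slope = 18000),
                                "T>100m" = c(intercept = 2200, slope = 20000),
                                "T<100m" = c(intercept = 3500, slope = 25000))) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (wetland_shape1 <= 0 || wetland_shape2 <= 0)
    stop("Beta parameters must be > 0")
  if (k_sdlog < 0 || area_sdlog < 0) stop("log-normal SDs must be >= 0")
  if (!all(CHANNEL_CLASSES %in% names(true_models)))
    stop("true_models must name all three channel classes")
  structure(list(n_cells = as.integer(n_cells), lat_range = lat_range,
                 wetland_shape1 = wetland_shape1, wetland_shape2 = wetland_shape2,
                 k_meanlog = k_meanlog, k_sdlog = k_sdlog,
                 area_small_meanlog = area_small_meanlog,
                 area_large_meanlog = area_large_meanlog,
                 area_sdlog = area_sdlog, true_models = true_models),
            class = "coscat_sim_config")
}

# wrap a c(intercept, slope) truth as a zero-uncertainty regression object
.true_regression <- function(pair, channel_class) {
  structure(list(channel_class = channel_class,
                 slope = unname(pair["slope"]), intercept = unname(pair["intercept"]),
                 se_slope = 0, se_intercept = 0, cov_slope_intercept = 0,
                 r_squared = 1, n_basins = NA_integer_),
            class = "wetland_regression")
}

#' Generate a synthetic COSCAT table with known true total
#'
#' Draws cells per the configuration and computes, analytically and with zero
#' noise, the tropical total implied by the configured true regression
#' models — enabling end-to-end recovery tests of the fitting, upscaling and
#' Monte Carlo stages.
#'
#' @param config A [coscat_sim_config()] object.
#' @param seed Integer seed.
#' @param constants A [gas_constants()] object used for the true total.
#' @return A list with `cells` (a COSCAT data.frame), `true_total_pgc_yr`
#'   (the deterministic tropical total under the true models), and
#'   `true_models` (the truths wrapped as zero-uncertainty regression
#'   objects).
#' @export
generate_coscat <- function(config, seed = 1L, constants = gas_constants()) {
  stopifnot(inherits(config, "coscat_sim_config"))
  set.seed(seed)
  n <- config$n_cells
  cells <- data.frame(
    coscat_id = sprintf("COSCAT_%04d", seq_len(n)),
    latitude = stats::runif(n, config$lat_range[1], config$lat_range[2]),
    wetland_fraction = stats::rbeta(n, config$wetland_shape1, config$wetland_shape2),
    k_small_m_d = stats::rlnorm(n, config$k_meanlog, config$k_sdlog),
    k_large_m_d = stats::rlnorm(n, config$k_meanlog, config$k_sdlog),
    area_small_km2 = stats::rlnorm(n, config$area_small_meanlog, config$area_sdlog),
    area_large_km2 = stats::rlnorm(n, config$area_large_meanlog, config$area_sdlog),
    stringsAsFactors = FALSE)
  true_models <- Map(.true_regression, config$true_models,
                     names(config$true_models))
  in_band <- cells$latitude >= -30 & cells$latitude <= 30
  true_total <- if (any(in_band)) {
    tropical_total(cells[in_band, , drop = FALSE], true_models,
                   constants)$total_pgc_yr
  } else 0
  list(cells = cells, true_total_pgc_yr = true_total,
       true_models = true_models)
}

#' Generate per-basin class medians from true wetland models
#'
#' Produces the basin points that feed [fit_wetland_regression()]: for each
#' basin (a wetland fraction) and channel class, the median pCO2 is the true
#' model prediction plus Gaussian noise — emulating sampling variability of
#' basin medians around the cross-basin trend.
#'
#' @param true_models Named list of `wetland_regression` objects (e.g. from
#'   [generate_coscat()]).
#' @param wetland_fractions Named numeric vector: basin -> wetland fraction.
#' @param noise_sd SD in ppm of the basin-median scatter around the trend.
#' @param seed Integer seed.
#' @return A basin-point data.frame suitable for [fit_wetland_regressions()].
#' @export
generate_basin_points <- function(true_models, wetland_fractions,
                                  noise_sd = 400, seed = 1L) {
  set.seed(seed)
  basins <- names(wetland_fractions)
  if (is.null(basins)) basins <- paste0("basin", seq_along(wetland_fractions))
  grid <- expand.grid(basin = basins, channel_class = CHANNEL_CLASSES,
                      stringsAsFactors = FALSE)
  wf <- wetland_fractions[grid$basin]
  mu <- mapply(function(cc, w)
    true_models[[cc]]$intercept + true_models[[cc]]$slope * w,
    grid$channel_class, wf)
  data.frame(basin = grid$basin, channel_class = grid$channel_class,
             median_pco2 = pmax(mu + stats::rnorm(nrow(grid), 0, noise_sd), 1),
             wetland_fraction = unname(wf),
             n_obs = NA_integer_, stringsAsFactors = FALSE)
}
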