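# Cross-basin regressions of median river-channel pCO2 on catchment wetland
# coverage, one per channel class, with coefficient covariance retained for
# Monte Carlo propagation.

#' Build basin points from class summaries and a wetland table
#'
#' Joins per-basin, per-class median pCO2 (from [summarize_measurements()])
#' with catchment wetland coverage fractions, producing one point per basin x
#' channel class for the cross-basin regressions.
#'
#' @param summaries A summary data.frame with columns `river`,
#'   `channel_class`, `n`, `pco2_median`.
#' @param wetland_table A data.frame with columns `basin` and
#'   `wetland_fraction` (in \[0, 1\]); a `units` column equal to `"percent"`
#'   triggers division by 100.
#' @return A data.frame with columns `basin, channel_class, median_pco2,
#'   wetland_fraction, n_obs`.
#' @export
build_basin_points <- function(summaries, wetland_table) {
  stopifnot(all(c("river", "channel_class", "n", "pco2_median") %in% names(summaries)),
            all(c("basin", "wetland_fraction") %in% names(wetland_table)))
  wf <- wetland_table$wetland_fraction
  if ("units" %in% names(wetland_table))
    wf <- ifelse(wetland_table$units == "percent", wf / 100, wf)
  if (any(wf < 0 | wf > 1))
    stop("wetland_fraction must lie in [0, 1] after unit conversion")
  lookup <- stats::setNames(wf, wetland_table$basin)
  if (nrow(summaries) == 0L)
    return(data.frame(basin = character(), channel_class = character(),
                      median_pco2 = numeric(), wetland_fraction = numeric(),
                      n_obs = integer()))
  missing <- setdiff(unique(summaries$river), names(lookup))
  if (length(missing))
    stop("no wetland fraction for basin(s): ", paste(missing, collapse = ", "))
  data.frame(basin = summaries$river,
             channel_class = summaries$channel_class,
             median_pco2 = summaries$pco2_median,
             wetland_fraction = unname(lookup[summaries$river]),
             n_obs = summaries$n)
}

#' Fit the wetland-coverage regression for one channel class
#'
#' Unweighted ordinary least squares of median pCO2 on wetland coverage
#' fraction across basins (basins contribute equally regardless of their
#' number of observations). Standard errors and the slope-intercept
#' covariance come from the standard OLS formulas and are retained for Monte
#' Carlo coefficient sampling.
#'
#' @param points A data.frame of basin points (see [build_basin_points()])
#'   for a single channel class; needs >= 3 basins with distinct wetland
#'   fractions.
#' @return An object of class `wetland_regression`: list with
#'   `channel_class`, `slope` (ppm per unit fraction), `intercept` (ppm),
#'   `se_slope`, `se_intercept`, `cov_slope_intercept`, `r_squared`,
#'   `n_basins`.
#' @export
fit_wetland_regression <- function(points) {
  stopifnot(all(c("median_pco2", "wetland_fraction") %in% names(points)))
  if (nrow(points) < 3L)
    stop("singular fit: need at least 3 basin points")
  if (length(unique(points$wetland_fraction)) < 2L ||
      stats::var(points$wetland_fraction) == 0)
    stop("singular fit: zero variance in wetland fraction")
  cc <- if ("channel_class" %in% names(points) &&
            length(unique(points$channel_class)) == 1L)
    points$channel_class[1L] else "unspecified"
  fit <- stats::lm(median_pco2 ~ wetland_fraction, data = points)
  # exactly collinear points are a legitimate input (SEs are then 0)
  sm <- .quiet_perfect_fit(summary(fit))
  vc <- .quiet_perfect_fit(stats::vcov(fit))
  structure(list(channel_class = cc,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 se_slope = sm$coefficients[2, 2],
                 se_intercept = sm$coefficients[1, 2],
                 cov_slope_intercept = vc[1, 2],
                 r_squared = sm$r.squared,
                 n_basins = nrow(points)),
            class = "wetland_regression")
}

#' Fit wetland regressions for all channel classes
#'
#' @param points Basin points for several channel classes.
#' @return Named list of [fit_wetland_regression()] objects, one per channel
#'   class present, named `MS`, `T>100m`, `T<100m`.
#' @export
fit_wetland_regressions <- function(points) {
  classes <- intersect(CHANNEL_CLASSES, unique(points$channel_class))
  stats::setNames(lapply(classes, function(cc)
    fit_wetland_regression(points[points$channel_class == cc, , drop = FALSE])),
    classes)
}

#' Predict river-channel pCO2 from wetland coverage
#'
#' Affine prediction `intercept + slope * wetland_fraction`. Predictions
#' below the floor (default 0 ppm: negative pCO2 is unphysical, but
#' sub-atmospheric values are legitimate and yield invasion fluxes) are
#' clamped; the number clamped is reported via a warning.
#'
#' @param model A `wetland_regression` object.
#' @param wetland_fraction Wetland coverage fraction(s) in \[0, 1\].
#' @param floor Lower clamp for predictions, in ppm. Default 0.
#' @return Predicted pCO2 in ppm. Vectorised.
#' @export
predict_pco2 <- function(model, wetland_fraction, floor = 0) {
  stopifnot(inherits(model, "wetland_regression"))
  if (any(wetland_fraction < 0 | wetland_fraction > 1))
    stop("wetland_fraction must lie in [0, 1]")
  p <- model$intercept + model$slope * wetland_fraction
  n_clamped <- sum(p < floor)
  if (n_clamped > 0) {
    warning(n_clamped, " prediction(s) below ", floor, " ppm clamped")
    p <- pmax(p, floor)
  }
  p
}

#' @export
print.wetland_regression <- function(x, ...) {
  cat(sprintf("median pCO2 ~ wetland fraction [%s]:\n", x$channel_class),
      sprintf("  slope     %.1f +/- %.1f ppm per unit fraction\n", x$slope, x$se_slope),
      sprintf("  intercept %.1f +/- %.1f ppm\n", x$intercept, x$se_intercept),
      sprintf("  r2 = %.3f over %d basins\n", x$r_squared, x$n_basins), sep = "")
  invisible(x)
}

#' Export fitted wetland regressions to JSON
#'
#' Writes all coefficient fields (including standard errors and covariance)
#' so the upscaling step is reproducible bit-exactly from the export.
#'
#' @param models Named list of `wetland_regression` objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_wetland_models <- function(models, path) {
  stopifnot(all(vapply(models, inherits, logical(1), "wetland_regression")))
  jsonlite::write_json(lapply(models, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read wetland regressions from a JSON export
#'
#' @param path JSON file written by [write_wetland_models()].
#' @return Named list of `wetland_regression` objects.
#' @export
read_wetland_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(m) structure(as.list(m), class = "wetland_regression"))
}
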