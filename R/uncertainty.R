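# Monte Carlo propagation of regression-coefficient, gas-transfer-velocity
# and surface-area uncertainties to the tropical total flux.

#' Monte Carlo configuration
#'
#' Settings for [mc_propagate()]. The relative SDs are 1-sigma relative
#' errors of multiplicative perturbations applied to the gas transfer
#' velocities and surface areas (`dist = "normal"`, truncated at zero), or
#' half-ranges of uniform perturbations (`dist = "uniform"`).
#' `error_correlation = "global"` draws one k perturbation and one area
#' perturbation per iteration, shared by all cells (systematic errors in the
#' underlying hydraulic relations shift all cells together and this choice is
#' the conservative one); `"independent"` draws per cell.
#'
#' @param n_iterations Number of Monte Carlo iterations (>= 1). Default 1000.
#' @param rel_sd_k Relative SD of the gas transfer velocity. Default 0.10.
#' @param rel_sd_area Relative SD of the surface areas. Default 0.31.
#' @param sample_coefficients Draw regression coefficients? Default TRUE.
#' @param use_coef_covariance Draw (slope, intercept) jointly from the fitted
#'   bivariate normal (TRUE, default) or as independent normals (FALSE).
#' @param dist `"normal"` (default) or `"uniform"` perturbations.
#' @param error_correlation `"global"` (default) or `"independent"`.
#' @param seed Integer seed; every random draw derives from it.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_iterations = 1000, rel_sd_k = 0.10,
                      rel_sd_area = 0.31, sample_coefficients = TRUE,
                      use_coef_covariance = TRUE,
                      dist = c("normal", "uniform"),
                      error_correlation = c("global", "independent"),
                      seed = 1L) {
  dist <- match.arg(dist)
  error_correlation <- match.arg(error_correlation)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (rel_sd_k < 0 || rel_sd_area < 0) stop("relative SDs must be >= 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 rel_sd_k = rel_sd_k, rel_sd_area = rel_sd_area,
                 sample_coefficients = isTRUE(sample_coefficients),
                 use_coef_covariance = isTRUE(use_coef_covariance),
                 dist = dist, error_correlation = error_correlation,
                 seed = as.integer(seed)),
            class = "mc_config")
}

# multiplicative perturbation draws: n x m matrix, mean 1
.perturb <- function(n, m, rel_sd, dist) {
  if (rel_sd == 0) return(matrix(1, n, m))
  if (dist == "uniform") {
    matrix(stats::runif(n * m, 1 - rel_sd, 1 + rel_sd), n, m)
  } else {
    x <- matrix(stats::rnorm(n * m, 1, rel_sd), n, m)
    while (any(bad <- x < 0))          # truncate at zero by redraw
      x[bad] <- stats::rnorm(sum(bad), 1, rel_sd)
    x
  }
}

# n draws of (intercept, slope) from one fitted wetland regression
.draw_coefficients <- function(model, n, use_covariance) {
  mu <- c(model$intercept, model$slope)
  if (use_covariance) {
    sigma <- matrix(c(model$se_intercept^2, model$cov_slope_intercept,
                      model$cov_slope_intercept, model$se_slope^2), 2, 2)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-12 * max(abs(ev), 1)) {
      warning("coefficient covariance not positive definite; ",
              "falling back to independent sampling")
      use_covariance <- FALSE
    }
  }
  if (use_covariance) {
    MASS::mvrnorm(n, mu = mu, Sigma = sigma)
  } else {
    cbind(stats::rnorm(n, mu[1], model$se_intercept),
          stats::rnorm(n, mu[2], model$se_slope))
  }
}

#' Monte Carlo propagation of the tropical total flux
#'
#' Per iteration: draws (slope, intercept) for each of the three wetland
#' regressions (jointly from the fitted bivariate normal, or independently),
#' draws multiplicative perturbations for the gas transfer velocities and
#' surface areas, recomputes the tropical total, and summarises the iteration
#' ensemble. Coefficient draws are shared across all cells within an
#' iteration (the regression is one model, not per-cell noise). Fully
#' reproducible from `config$seed`.
#'
#' @param cells A COSCAT data.frame.
#' @param models Named list of the three `wetland_regression` objects.
#' @param constants A [gas_constants()] object.
#' @param config An [mc_config()] object.
#' @param lat_band Inclusive latitude band; default `c(-30, 30)`.
#' @return An object of class `mc_result`: list with `mean`, `sd`, `p2.5`,
#'   `p50`, `p97.5` (Pg C yr-1), `deterministic_total_pgc_yr`,
#'   `n_iterations`, `seed` and the echoed `config`.
#' @export
mc_propagate <- function(cells, models, constants = gas_constants(),
                         config = mc_config(), lat_band = c(-30, 30)) {
  stopifnot(inherits(config, "mc_config"),
            all(CHANNEL_CLASSES %in% names(models)))
  validate_coscat(cells)
  det <- tropical_total(cells, models, constants, lat_band)
  band <- cells[cells$latitude >= lat_band[1] & cells$latitude <= lat_band[2],
                , drop = FALSE]
  n_it <- config$n_iterations
  if (nrow(band) == 0L) {
    totals <- rep(0, n_it)
  } else {
    set.seed(config$seed)
    alpha <- co2_solubility(constants$water_temp, constants$salinity)
    wf <- band$wetland_fraction
    m <- nrow(band)

    if (config$sample_coefficients) {
      co <- lapply(models[CHANNEL_CLASSES], .draw_coefficients, n = n_it,
                   use_covariance = config$use_coef_covariance)
    } else {
      co <- lapply(models[CHANNEL_CLASSES], function(mod)
        matrix(c(mod$intercept, mod$slope), n_it, 2, byrow = TRUE))
    }
    # n_it x m predicted pCO2 matrices, clamped at 0 ppm
    pred <- function(cf) pmax(cf[, 1] + cf[, 2] %o% wf, 0)
    p_small <- pred(co[["T<100m"]])
    p_msT <- (pred(co[["MS"]]) + pred(co[["T>100m"]])) / 2

    mm <- if (config$error_correlation == "global") 1L else m
    eps_k <- .perturb(n_it, mm, config$rel_sd_k, config$dist)
    eps_a <- .perturb(n_it, mm, config$rel_sd_area, config$dist)
    if (mm == 1L) {
      eps_k <- eps_k[, rep(1L, m), drop = FALSE]
      eps_a <- eps_a[, rep(1L, m), drop = FALSE]
    }
    # areal fluxes (mmol m-2 d-1) and integrated totals, per iteration x cell
    f_small <- sweep(p_small - constants$atm_pco2, 2,
                     alpha * band$k_small_m_d, `*`) * eps_k
    f_large <- sweep(p_msT - constants$atm_pco2, 2,
                     alpha * band$k_large_m_d, `*`) * eps_k
    per_cell <- sweep(f_small, 2, band$area_small_km2, `*`) +
      sweep(f_large, 2, band$area_large_km2, `*`)
    conv <- 1e-3 * 1e6 * 365.25 * 12.011 * 1e-15   # as areal_to_integrated
    totals <- rowSums(per_cell * eps_a) * conv
  }
  q <- stats::quantile(totals, c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(mean = mean(totals), sd = stats::sd(totals),
                 p2.5 = q[1], p50 = q[2], p97.5 = q[3],
                 deterministic_total_pgc_yr = det$total_pgc_yr,
                 n_iterations = n_it, seed = config$seed, config = config),
            class = "mc_result")
}

#' Render a Monte Carlo result as "mean +/- sd"
#'
#' @param result An `mc_result` object.
#' @param decimals Decimal places used for the rounding. Default 1.
#' @return A single string, e.g. `"1.8 ± 0.4 PgC yr-1 (2.5-97.5%: 1.0-2.7)"`.
#' @export
summarize_mc <- function(result, decimals = 1) {
  stopifnot(inherits(result, "mc_result"))
  fmt <- paste0("%.", decimals, "f")
  sprintf(paste0(fmt, " ± ", fmt, " PgC yr-1 (2.5-97.5%%: ", fmt, "-", fmt, ")"),
          round(result$mean, decimals), round(result$sd, decimals),
          round(result$p2.5, decimals), round(result$p97.5, decimals))
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte Carlo tropical total flux (", x$n_iterations, " iterations, seed ",
      x$seed, "):\n  ", summarize_mc(x), "\n  deterministic total: ",
      signif(x$deterministic_total_pgc_yr, 4), " PgC yr-1\n", sep = "")
  invisible(x)
}
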