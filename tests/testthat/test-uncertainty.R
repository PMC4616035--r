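# Monte Carlo propagation of regression, k and area uncertainties.

test_that("all uncertainties at zero degenerate to the deterministic total", {
  sim <- generate_coscat(coscat_sim_config(n_cells = 20), seed = 6)
  cfg <- mc_config(n_iterations = 200, rel_sd_k = 0, rel_sd_area = 0,
                   sample_coefficients = FALSE, seed = 1)
  res <- mc_propagate(sim$cells, sim$true_models, config = cfg)
  expect_identical(res$sd, 0)
  expect_equal(res$mean, res$deterministic_total_pgc_yr, tolerance = 1e-14)
  expect_equal(res$p2.5, res$p97.5)
})

test_that("area-only uncertainty passes its relative SD through the linear flux", {
  cellt <- single_cell()
  models <- toy_models()
  cfg <- mc_config(n_iterations = 1e5, rel_sd_k = 0, rel_sd_area = 0.31,
                   sample_coefficients = FALSE, seed = 42)
  res <- mc_propagate(cellt, models, config = cfg)
  # flux is linear in area, so the ensemble relative SD equals 0.31 up to
  # Monte Carlo error (and slight zero-truncation, well under 1% at 0.31)
  expect_lt(abs(res$sd / res$mean - 0.31), 0.01)
  expect_equal(res$mean, res$deterministic_total_pgc_yr, tolerance = 0.01)
})

test_that("small-sigma MC spread agrees with first-order delta-method propagation", {
  cellt <- single_cell(wf = 0.2, k_small = 2, k_large = 0,
                       a_small = 100, a_large = 0)
  # only the T<100m model matters (k_large = 0); give it coefficient SEs
  models <- toy_models()
  models[["T<100m"]]$se_intercept <- 60
  models[["T<100m"]]$se_slope <- 300
  models[["T<100m"]]$cov_slope_intercept <- 0
  sk <- 0.03; sa <- 0.03
  cfg <- mc_config(n_iterations = 1e5, rel_sd_k = sk, rel_sd_area = sa,
                   sample_coefficients = TRUE, use_coef_covariance = TRUE,
                   seed = 7)
  res <- mc_propagate(cellt, models, config = cfg)
  # first-order: F ~ k*A*(p - p_atm); var terms from p (through sigma_pCO2),
  # k and A, all relative to the mean
  p <- models[["T<100m"]]$intercept + models[["T<100m"]]$slope * 0.2
  sigma_p <- sqrt(60^2 + (300 * 0.2)^2)
  rel <- sqrt((sigma_p / (p - 390))^2 + sk^2 + sa^2)
  expect_lt(abs(res$sd / res$mean - rel) / rel, 0.10)
})

test_that("the ensemble is reproducible from the seed and ordered in its percentiles", {
  sim <- generate_coscat(coscat_sim_config(n_cells = 15), seed = 3)
  models <- toy_models()
  cfg <- mc_config(n_iterations = 500, seed = 123)
  r1 <- mc_propagate(sim$cells, models, config = cfg)
  r2 <- mc_propagate(sim$cells, models, config = cfg)
  expect_identical(r1$mean, r2$mean)
  expect_identical(r1$sd, r2$sd)
  expect_identical(r1$p50, r2$p50)
  expect_true(r1$p2.5 <= r1$p50 && r1$p50 <= r1$p97.5)
  r3 <- mc_propagate(sim$cells, models, config = mc_config(500, seed = 124))
  expect_false(identical(r1$mean, r3$mean))
})

test_that("increasing any single relative SD does not decrease the ensemble sd", {
  sim <- generate_coscat(coscat_sim_config(n_cells = 10), seed = 5)
  models <- toy_models()
  sd_at <- function(k, a) mc_propagate(
    sim$cells, models,
    config = mc_config(n_iterations = 1e4, rel_sd_k = k, rel_sd_area = a,
                       sample_coefficients = FALSE, seed = 11))$sd
  expect_lte(sd_at(0.05, 0), sd_at(0.10, 0) * 1.02)
  expect_lte(sd_at(0, 0.10), sd_at(0, 0.31) * 1.02)
  expect_identical(sd_at(0, 0), 0)
})

test_that("independent per-cell errors give a smaller spread than global errors", {
  sim <- generate_coscat(coscat_sim_config(n_cells = 40), seed = 14)
  models <- toy_models()
  base <- list(n_iterations = 4000, rel_sd_k = 0.10, rel_sd_area = 0.31,
               sample_coefficients = FALSE, seed = 20)
  r_glob <- mc_propagate(sim$cells, models,
                         config = do.call(mc_config, c(base, error_correlation = "global")))
  r_ind <- mc_propagate(sim$cells, models,
                        config = do.call(mc_config, c(base, error_correlation = "independent")))
  expect_lt(r_ind$sd, r_glob$sd)
})

test_that("uniform perturbations honour the half-range interpretation", {
  cellt <- single_cell()
  models <- toy_models()
  cfg <- mc_config(n_iterations = 2e4, rel_sd_k = 0, rel_sd_area = 0.31,
                   sample_coefficients = FALSE, dist = "uniform", seed = 2)
  res <- mc_propagate(cellt, models, config = cfg)
  det <- res$deterministic_total_pgc_yr
  # uniform on [0.69, 1.31] x deterministic: bounded support, sd = 0.31/sqrt(3)
  expect_gt(res$p2.5, det * 0.69 * 0.999)
  expect_lt(res$p97.5, det * 1.31 * 1.001)
  expect_lt(abs(res$sd / res$mean - 0.31 / sqrt(3)), 0.01)
})

test_that("non-positive-definite coefficient covariance falls back with a warning", {
  cellt <- single_cell()
  models <- toy_models()
  m <- models[["T<100m"]]
  m$se_intercept <- 50; m$se_slope <- 100
  m$cov_slope_intercept <- -2 * 50 * 100      # |rho| = 2: impossible
  models[["T<100m"]] <- m
  cfg <- mc_config(n_iterations = 50, rel_sd_k = 0, rel_sd_area = 0, seed = 3)
  expect_warning(res <- mc_propagate(cellt, models, config = cfg),
                 "not positive definite")
  expect_true(is.finite(res$mean))
})

test_that("summarize_mc renders mean +/- sd with the configured rounding", {
  res <- structure(list(mean = 1.7812, sd = 0.4419, p2.5 = 1.02, p50 = 1.77,
                        p97.5 = 2.71, deterministic_total_pgc_yr = 1.78,
                        n_iterations = 1000L, seed = 1L, config = NULL),
                   class = "mc_result")
  txt <- summarize_mc(res, 1)
  expect_match(txt, "1.8 ± 0.4", fixed = TRUE)
  expect_match(txt, "1.0-2.7", fixed = TRUE)
  res$sd <- 0
  expect_match(summarize_mc(res, 1), "± 0.0", fixed = TRUE)
})
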