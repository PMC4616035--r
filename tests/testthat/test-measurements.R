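# Reading/validation, stratification, rank tests, log-linear CH4~pCO2 fits.

test_that("reader accepts well-formed rows and rejects invariant violations with counts", {
  path <- write_measurement_csv(minimal_measurements())
  rec <- read_measurements(path)
  expect_equal(nrow(rec), 3L)
  expect_s3_class(rec$date, "Date")
  expect_true(all(attr(rec, "rejections") == 0L))

  bad <- minimal_measurements()
  bad$ch4_nmol_l[2] <- 0
  bad$pco2_ppm[3] <- -10
  bad <- rbind(bad, data.frame(river = "Congo", date = "2014-06-10",
                               longitude = 16, latitude = -1,
                               channel_class = "lake", pco2_ppm = 5000,
                               ch4_nmol_l = 100))
  rec2 <- read_measurements(write_measurement_csv(bad))
  expect_equal(nrow(rec2), 1L)
  rej <- attr(rec2, "rejections")
  expect_equal(unname(rej["nonpositive_ch4"]), 1L)
  expect_equal(unname(rej["nonpositive_pco2"]), 1L)
  expect_equal(unname(rej["bad_channel_class"]), 1L)
})

test_that("reader errors name missing columns and counts unparseable numerics", {
  d <- minimal_measurements()
  d$pco2_ppm <- NULL
  expect_error(read_measurements(write_measurement_csv(d)), "pco2_ppm")
  d2 <- minimal_measurements()
  d2$ch4_nmol_l[1] <- "not-a-number"
  expect_message(rec <- read_measurements(write_measurement_csv(d2)), "line")
  expect_equal(nrow(rec), 2L)
  expect_equal(unname(attr(rec, "rejections")["unparseable_numeric"]), 1L)
})

test_that("optional source column excludes digitized rows by default", {
  d <- minimal_measurements()
  d$source <- c("primary", "digitized", "primary")
  rec <- read_measurements(write_measurement_csv(d))
  expect_equal(nrow(rec), 2L)
  expect_equal(unname(attr(rec, "rejections")["excluded_source"]), 1L)
  rec_all <- read_measurements(write_measurement_csv(d),
                               sources = c("primary", "digitized"))
  expect_equal(nrow(rec_all), 3L)
})

test_that("channel classification follows the 100 m threshold with mainstem dominance", {
  expect_equal(classify_channel(150, FALSE), "T>100m")
  expect_equal(classify_channel(40, FALSE), "T<100m")
  expect_equal(classify_channel(100, FALSE), "T>100m")   # tie owned by T>100m
  expect_equal(classify_channel(NA, TRUE), "MS")
  expect_equal(classify_channel(c(150, 40), c(FALSE, TRUE)),
               c("T>100m", "MS"))
  expect_error(classify_channel(-5, FALSE), "positive")
})

test_that("stratum summaries respect order-statistic ordering and are permutation invariant", {
  cfg <- two_basin_config()
  m <- generate_measurements(cfg, seed = 11)
  s <- summarize_measurements(m)
  expect_equal(nrow(s), 6L)
  expect_equal(sum(s$n), nrow(m))
  for (g in c("pco2", "ch4")) {
    cols <- paste0(g, "_", c("min", "p5", "q25", "median", "q75", "p95", "max"))
    ord <- as.matrix(s[cols])
    expect_true(all(t(apply(ord, 1, diff)) >= 0))
  }
  shuffled <- m[sample(nrow(m)), ]
  expect_equal(summarize_measurements(shuffled), s)
  # single record: all statistics collapse to that value
  one <- m[1, , drop = FALSE]
  s1 <- summarize_measurements(one)
  expect_equal(s1$pco2_median, one$pco2)
  expect_equal(s1$pco2_min, one$pco2)
  expect_equal(s1$pco2_max, one$pco2)
  expect_equal(s1$pco2_mean, one$pco2)
  expect_error(summarize_measurements(m[0, ]), "empty stratum")
})

test_that("large synthetic stratum reproduces its configured median", {
  cfg <- stratum_config("X", "MS", 1001, median_pco2 = 4000, gsd_pco2 = 1.8,
                        ch4_slope = 1e-4, ch4_intercept = 2,
                        ch4_log_noise_sd = 0.3)
  m <- generate_measurements(cfg, seed = 42)
  s <- summarize_measurements(m)
  expect_lt(abs(s$pco2_median - 4000) / 4000, 0.05)
})

test_that("basin ranges pool all classes of a river", {
  m <- generate_measurements(two_basin_config(), seed = 3)
  r <- basin_ranges(m)
  for (i in seq_len(nrow(r))) {
    sub <- m[m$river == r$river[i], ]
    expect_equal(r$pco2_min[i], min(sub$pco2))
    expect_equal(r$ch4_max[i], max(sub$ch4))
    expect_equal(r$n[i], nrow(sub))
  }
})

test_that("Kruskal-Wallis matches the hand-ranked oracle and handles degenerate ties", {
  # 3 groups of 4 small integers; H frozen from an independent ranking
  vals <- c(1, 3, 5, 7, 2, 4, 6, 8, 10, 11, 12, 13)
  grp <- rep(c("a", "b", "c"), each = 4)
  kw <- kruskal_wallis(vals, grp)
  expect_equal(kw$H, 7.53846153846154, tolerance = 1e-10)
  expect_equal(kw$p_value, 0.0230698024654865, tolerance = 1e-8)
  # identical groups: H ~ 0, p ~ 1
  kw0 <- kruskal_wallis(rep(c(5, 6, 7), 3), rep(c("a", "b", "c"), each = 3))
  expect_lt(kw0$H, 1e-8)
  expect_gt(kw0$p_value, 0.999)
  # all observations tied: finite statistic, no 0/0 blowup
  kwt <- kruskal_wallis(rep(1, 9), rep(c("a", "b", "c"), each = 3))
  expect_identical(kwt$H, 0)
  expect_identical(kwt$p_value, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("Mann-Whitney matches exhaustive enumeration for small untied samples", {
  a <- c(1.2, 3.4, 2.2, 5.0)
  b <- c(4.1, 6.3, 0.5, 7.7)
  mw <- mann_whitney(a, b)
  expect_true(mw$exact)
  expect_equal(mw$p_value, mw_enumerate_p(a, b), tolerance = 1e-12)
  expect_equal(mw$p_value, 34 / 70, tolerance = 1e-12)   # frozen enumeration
  # several random small cases against the enumeration oracle
  set.seed(99)
  for (i in 1:8) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    x <- sample(seq(0.1, 50, by = 0.1), na + nb)  # distinct values
    aa <- x[seq_len(na)]; bb <- x[-seq_len(na)]
    expect_equal(mann_whitney(aa, bb)$p_value, mw_enumerate_p(aa, bb),
                 tolerance = 1e-12, info = paste("case", i))
  }
  # complete separation gives an extreme U
  sep <- mann_whitney(1:4, 11:14)
  expect_true(sep$U %in% c(0, 16))
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("two-group Kruskal-Wallis orders datasets like the Mann-Whitney deviation", {
  set.seed(7)
  stats_pairs <- t(replicate(12, {
    a <- rnorm(9); b <- rnorm(9, mean = runif(1, 0, 2))
    kw <- kruskal_wallis(c(a, b), rep(c("a", "b"), each = 9))
    mw <- mann_whitney(a, b)
    c(H = kw$H, dev = abs(mw$U - length(a) * length(b) / 2))
  }))
  expect_equal(order(stats_pairs[, "H"]), order(stats_pairs[, "dev"]))
})

test_that("log10(CH4) ~ pCO2 fit recovers exact and noisy generating lines", {
  # exact line: r2 = 1 and exact coefficients
  pco2 <- c(500, 1500, 3000, 6000, 9000)
  d <- data.frame(river = "X", channel_class = "MS", pco2 = pco2,
                  ch4 = 10^(1.5 + 2e-4 * pco2))
  fit <- fit_log_ch4_vs_pco2(d)
  expect_equal(fit$slope, 2e-4, tolerance = 1e-10)
  expect_equal(fit$intercept, 1.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # noisy synthetic stratum: slope within 2 SE of truth; negative coupling
  cfg <- rbind(
    stratum_config("A", "MS", 400, 4000, 1.6, -5e-5, 2.4, 0.25),
    stratum_config("A", "T<100m", 400, 7000, 1.8, 1.2e-4, 1.7, 0.3))
  m <- generate_measurements(cfg, seed = 5)
  f_ms <- fit_log_ch4_vs_pco2(m, "A", "MS")
  expect_lt(abs(f_ms$slope - (-5e-5)), 2 * f_ms$se_slope)
  expect_lt(f_ms$slope, 0)
  f_sm <- fit_log_ch4_vs_pco2(m, "A", "T<100m")
  expect_lt(abs(f_sm$slope - 1.2e-4), 2 * f_sm$se_slope)
  # degenerate pCO2
  dd <- data.frame(river = "X", channel_class = "MS",
                   pco2 = rep(1000, 5), ch4 = c(10, 20, 30, 40, 50))
  expect_error(fit_log_ch4_vs_pco2(dd), "singular")
  expect_error(fit_log_ch4_vs_pco2(d[1:2, ]), "at least 3")
})

test_that("between-river comparison reports direction and p per class", {
  m <- generate_measurements(two_basin_config(), seed = 21)
  cmp <- compare_rivers(m, "ch4")
  expect_equal(sort(cmp$channel_class), sort(CHANNEL_CLASSES))
  expect_true(all(c("p_value", "higher") %in% names(cmp)))
})
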