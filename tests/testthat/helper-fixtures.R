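# Shared fixtures, built in code.

# small measurement CSV on disk; returns the path
write_measurement_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# a minimal well-formed measurement table
minimal_measurements <- function() {
  data.frame(river = c("Amazon", "Amazon", "Congo"),
             date = c("2008-05-11", "2008-05-12", "2013-12-03"),
             longitude = c(-60.9, -60.5, 16.2),
             latitude = c(-3.4, -3.2, -1.5),
             channel_class = c("MS", "T<100m", "T>100m"),
             pco2_ppm = c(4350, 7600, 3900),
             ch4_nmol_l = c(120, 800, 450))
}

# single-cell COSCAT table with hand-checkable numbers
single_cell <- function(lat = 0, wf = 0.2, k_small = 2, k_large = 3,
                        a_small = 100, a_large = 200) {
  data.frame(coscat_id = "C1", latitude = lat, wetland_fraction = wf,
             k_small_m_d = k_small, k_large_m_d = k_large,
             area_small_km2 = a_small, area_large_km2 = a_large,
             stringsAsFactors = FALSE)
}

# three zero-uncertainty regressions with chosen coefficients
toy_models <- function(ms = c(1000, 10000), t_large = c(2000, 12000),
                       t_small = c(3000, 15000)) {
  mk <- function(cc, ic, sl) structure(
    list(channel_class = cc, slope = sl, intercept = ic, se_slope = 0,
         se_intercept = 0, cov_slope_intercept = 0, r_squared = 1,
         n_basins = 3L),
    class = "wetland_regression")
  list("MS" = mk("MS", ms[1], ms[2]),
       "T>100m" = mk("T>100m", t_large[1], t_large[2]),
       "T<100m" = mk("T<100m", t_small[1], t_small[2]))
}

# exhaustive two-sided Mann-Whitney p-value by enumerating all rank splits
mw_enumerate_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(n, na)
  u_all <- apply(splits, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}
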