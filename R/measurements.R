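# Reading, validation, stratification and statistics for the paired
# pCO2/CH4 data-set.

#' The three channel classes
#'
#' River networks are stratified into the mainstem (`"MS"`), large
#' tributaries wider than 100 m (`"T>100m"`) and small tributaries narrower
#' than 100 m (`"T<100m"`).
#' @export
CHANNEL_CLASSES <- c("MS", "T>100m", "T<100m")

#' Classify a channel by width
#'
#' Assigns a channel class from the width and a mainstem flag. The mainstem
#' flag dominates; otherwise channels at least 100 m wide are large
#' tributaries and narrower channels small tributaries (a width of exactly
#' 100 m is assigned to `"T>100m"`).
#'
#' @param width Channel width in metres (> 0; ignored for the mainstem).
#' @param is_mainstem Logical; is this the mainstem?
#' @return One of `"MS"`, `"T>100m"`, `"T<100m"`. Vectorised.
#' @examples
#' classify_channel(150, FALSE)
#' classify_channel(40, FALSE)
#' classify_channel(NA, TRUE)
#' @export
classify_channel <- function(width, is_mainstem = FALSE) {
  n <- max(length(width), length(is_mainstem))
  width <- rep_len(width, n)
  is_mainstem <- rep_len(is_mainstem, n)
  if (any(!is_mainstem & (!is.finite(width) | width <= 0)))
    stop("width must be a positive number for non-mainstem channels")
  ifelse(is_mainstem, "MS", ifelse(width >= 100, "T>100m", "T<100m"))
}

#' Read and validate paired pCO2/CH4 measurement records
#'
#' Reads a delimited text file of geo-referenced, timestamped paired pCO2 and
#' dissolved CH4 measurements. Required columns:
#' `river, date, longitude, latitude, channel_class, pco2_ppm, ch4_nmol_l`;
#' optional `source` and `width_m`. Dates are ISO-8601; coordinates decimal
#' degrees (east/north positive). Rows violating the record invariants
#' (pCO2 <= 0, CH4 <= 0 — both gases must be positive for the log
#' transforms — unknown channel class, or unparseable numerics) are rejected,
#' counted and reported per reason in the `rejections` attribute.
#'
#' @param path Path to a CSV file.
#' @param sources Character vector of `source` labels to keep when the file
#'   has a `source` column; defaults to `"primary"` so that digitised
#'   literature values (e.g. `source = "digitized"`) are excluded unless
#'   requested.
#' @return A data.frame of validated records with columns `river`, `date`
#'   (Date), `longitude`, `latitude`, `channel_class`, `pco2`, `ch4` (and
#'   `source`, `width_m` when present), with attribute `rejections` (a named
#'   integer vector of rejection counts by reason).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(river = "Amazon", date = "2008-05-11",
#'                      longitude = -60.9, latitude = -3.4,
#'                      channel_class = "MS", pco2_ppm = 4300,
#'                      ch4_nmol_l = 120),
#'           f, row.names = FALSE)
#' read_measurements(f)
#' @export
read_measurements <- function(path, sources = "primary") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  required <- c("river", "date", "longitude", "latitude", "channel_class",
                "pco2_ppm", "ch4_nmol_l")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))

  rej <- c(unparseable_numeric = 0L, nonpositive_pco2 = 0L,
           nonpositive_ch4 = 0L, bad_channel_class = 0L,
           excluded_source = 0L)
  if ("source" %in% names(raw) && !is.null(sources)) {
    keep <- raw$source %in% sources
    rej["excluded_source"] <- sum(!keep)
    raw <- raw[keep, , drop = FALSE]
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  pco2 <- num(raw$pco2_ppm)
  ch4 <- num(raw$ch4_nmol_l)
  lon <- num(raw$longitude)
  lat <- num(raw$latitude)

  bad_num <- is.na(pco2) | is.na(ch4) | is.na(lon) | is.na(lat)
  if (any(bad_num)) {
    rej["unparseable_numeric"] <- sum(bad_num)
    for (i in which(bad_num))
      message("rejected line ", i + 1L, ": unparseable numeric value")
  }
  bad_pco2 <- !bad_num & pco2 <= 0
  bad_ch4 <- !bad_num & !bad_pco2 & ch4 <= 0
  bad_class <- !bad_num & !bad_pco2 & !bad_ch4 &
    !(raw$channel_class %in% CHANNEL_CLASSES)
  rej["nonpositive_pco2"] <- sum(bad_pco2)
  rej["nonpositive_ch4"] <- sum(bad_ch4)
  rej["bad_channel_class"] <- sum(bad_class)
  keep <- !(bad_num | bad_pco2 | bad_ch4 | bad_class)

  out <- data.frame(river = raw$river[keep],
                    date = as.Date(raw$date[keep]),
                    longitude = lon[keep],
                    latitude = lat[keep],
                    channel_class = raw$channel_class[keep],
                    pco2 = pco2[keep],
                    ch4 = ch4[keep],
                    stringsAsFactors = FALSE)
  if ("source" %in% names(raw)) out$source <- raw$source[keep]
  if ("width_m" %in% names(raw)) out$width_m <- num(raw$width_m)[keep]
  attr(out, "rejections") <- rej
  out
}

# exactly collinear data are legitimate test inputs; keep lm's perfect-fit
# warning out of the way for that case only
.quiet_perfect_fit <- function(expr) withCallingHandlers(expr,
  warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })

# order statistics for one stratum; type-7 (linear interpolation) quantiles
.stat_row <- function(x) {
  q <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                       names = FALSE)
  c(n = length(x), median = q[3], mean = mean(x), q25 = q[2], q75 = q[4],
    p5 = q[1], p95 = q[5], min = min(x), max = max(x))
}

#' Summarise measurements per river and channel class
#'
#' Descriptive statistics of pCO2 and CH4 per stratum (river x channel
#' class, or any subset of those grouping variables): n, median, mean,
#' quartiles, 5-95 percentiles, min and max, computed on the raw
#' (untransformed) values with type-7 (linear interpolation) percentiles.
#'
#' @param records A measurement data.frame as returned by
#'   [read_measurements()] or [generate_measurements()].
#' @param by Grouping columns; default `c("river", "channel_class")`.
#' @return A data.frame with one row per non-empty stratum and columns
#'   `<by>, n, pco2_median, pco2_mean, pco2_q25, ..., ch4_max`.
#' @export
summarize_measurements <- function(records, by = c("river", "channel_class")) {
  stopifnot(all(by %in% names(records)), all(c("pco2", "ch4") %in% names(records)))
  if (nrow(records) == 0L) stop("empty stratum: no records to summarize")
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  groups <- split(records, key)
  rows <- lapply(groups, function(g) {
    sp <- .stat_row(g$pco2)
    sc <- .stat_row(g$ch4)
    cbind(g[1L, by, drop = FALSE],
          data.frame(n = unname(sp["n"]),
                     t(stats::setNames(sp[-1], paste0("pco2_", names(sp)[-1]))),
                     t(stats::setNames(sc[-1], paste0("ch4_", names(sc)[-1])))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Basin-wide concentration ranges
#'
#' Minimum and maximum pCO2 and CH4 per river, pooled across all channel
#' classes (the convention for reporting a single basin-wide range).
#'
#' @param records A measurement data.frame.
#' @return A data.frame with columns `river, pco2_min, pco2_max, ch4_min,
#'   ch4_max, n`.
#' @export
basin_ranges <- function(records) {
  groups <- split(records, records$river)
  out <- do.call(rbind, lapply(groups, function(g)
    data.frame(river = g$river[1L],
               pco2_min = min(g$pco2), pco2_max = max(g$pco2),
               ch4_min = min(g$ch4), ch4_max = max(g$ch4),
               n = nrow(g))))
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank test across channel classes
#'
#' Rank-based comparison of a variable across two or more groups, with tie
#' correction and the chi-square approximation for the p-value.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values` (>= 2 distinct
#'   groups).
#' @return A list with `H` (tie-corrected statistic), `df`, `p_value` and
#'   `n`.
#' @examples
#' kruskal_wallis(c(1, 3, 5, 7, 2, 4, 6, 8, 10, 11, 12, 13),
#'                rep(c("a", "b", "c"), each = 4))
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  if (length(unique(values)) == 1L) {
    # all observations tied: the tie-corrected statistic degenerates to 0/0;
    # the limit of "no evidence against equality" is H = 0, p = 1
    return(list(H = 0, df = nlevels(groups) - 1L, p_value = 1,
                n = length(values)))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = length(values))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided two-sample rank test with tie correction. For small samples
#' (both n <= 50) without ties the p-value is the exact permutation value;
#' otherwise the normal approximation with continuity and tie correction is
#' used.
#'
#' @param sample_a,sample_b Non-empty numeric samples.
#' @return A list with `U` (the Mann-Whitney statistic for `sample_a`),
#'   `p_value`, `n_a`, `n_b` and `exact` (logical; whether the exact
#'   distribution was used).
#' @examples
#' mann_whitney(c(1.2, 3.4, 2.2, 5.0), c(4.1, 6.3, 0.5, 7.7))
#' @export
mann_whitney <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be non-empty")
  has_ties <- anyDuplicated(c(sample_a, sample_b)) > 0L
  exact <- !has_ties && length(sample_a) <= 50L && length(sample_b) <= 50L
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(sample_a), n_b = length(sample_b), exact = exact)
}

#' Pairwise between-river comparisons per channel class
#'
#' For each channel class present in both rivers, runs a two-sided
#' Mann-Whitney test of the chosen gas between the two rivers and reports the
#' direction of the median difference.
#'
#' @param records A measurement data.frame covering exactly two rivers.
#' @param variable `"pco2"` or `"ch4"`.
#' @return A data.frame with one row per channel class: `channel_class,
#'   median_<river1>, median_<river2>, U, p_value, higher` (the river with
#'   the larger median).
#' @export
compare_rivers <- function(records, variable = c("pco2", "ch4")) {
  variable <- match.arg(variable)
  rivers <- sort(unique(records$river))
  if (length(rivers) != 2L) stop("compare_rivers needs exactly 2 rivers")
  classes <- intersect(CHANNEL_CLASSES, unique(records$channel_class))
  rows <- lapply(classes, function(cc) {
    a <- records[records$river == rivers[1] & records$channel_class == cc, variable]
    b <- records[records$river == rivers[2] & records$channel_class == cc, variable]
    if (!length(a) || !length(b)) return(NULL)
    mw <- mann_whitney(a, b)
    data.frame(channel_class = cc, median_a = stats::median(a),
               median_b = stats::median(b), U = mw$U, p_value = mw$p_value,
               higher = if (stats::median(a) >= stats::median(b)) rivers[1] else rivers[2])
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "median_a"] <- paste0("median_", rivers[1])
  names(out)[names(out) == "median_b"] <- paste0("median_", rivers[2])
  rownames(out) <- NULL
  out
}

#' Log-linear regression of CH4 on pCO2
#'
#' Ordinary least squares of log10(CH4) on untransformed pCO2 within one
#' stratum (river x channel class), as used to characterise the coupling of
#' the two gases along river networks.
#'
#' @param records A measurement data.frame.
#' @param river River to subset, or `NULL` to use all rows.
#' @param channel_class Channel class to subset, or `NULL`.
#' @return An object of class `loglinear_fit`: list with `river`,
#'   `channel_class`, `slope` (per ppm), `intercept` (log10 nmol/L),
#'   `se_slope`, `r_squared`, `n`.
#' @export
fit_log_ch4_vs_pco2 <- function(records, river = NULL, channel_class = NULL) {
  d <- records
  if (!is.null(river)) d <- d[d$river == river, , drop = FALSE]
  if (!is.null(channel_class))
    d <- d[d$channel_class == channel_class, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 records in the stratum")
  if (stats::var(d$pco2) == 0)
    stop("singular fit: zero variance in pCO2")
  fit <- stats::lm(log10(ch4) ~ pco2, data = d)
  sm <- .quiet_perfect_fit(summary(fit))
  structure(list(river = river %||% "all", channel_class = channel_class %||% "all",
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 se_slope = sm$coefficients[2, 2],
                 r_squared = sm$r.squared, n = nrow(d)),
            class = "loglinear_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.loglinear_fit <- function(x, ...) {
  cat(sprintf("log10(CH4) ~ pCO2 [%s / %s]: slope = %.3g per ppm, intercept = %.3g, r2 = %.3f, n = %d\n",
              x$river, x$channel_class, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}
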