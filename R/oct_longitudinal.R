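# Longitudinal OCT pachymetry: baseline-relative change, per-day paired
# tests against the day -1 baseline, and peak/recovery characterization of
# the post-injury swelling curve. The module analyses whatever thickness
# field the series carries; label the layer in downstream reports.

check_oct <- function(oct) {
  need <- c("animal_id", "region", "day", "thickness_um")
  miss <- setdiff(need, names(oct))
  if (length(miss))
    stopf("OCT table lacks column(s): %s", paste(miss, collapse = ", "))
  key <- interaction(oct$animal_id, oct$region, drop = TRUE)
  dup <- tapply(oct$day, key, anyDuplicated)
  if (any(unlist(dup) > 0)) stopf("duplicate days within an (animal, region) series")
  invisible(oct)
}

#' Thickness as percent of the day -1 baseline
#'
#' `percent = 100 * thickness(day) / thickness(-1)` per (animal, region)
#' series; the baseline day maps to exactly 100. Invariant under rescaling
#' all thicknesses by a positive constant.
#'
#' @param oct OCT tibble (`animal_id`, `region`, `day`, `thickness_um`)
#'   including day -1.
#' @return The input with an added `percent_of_baseline` column.
#' @export
percent_of_baseline <- function(oct) {
  check_oct(oct)
  out <- oct
  out$percent_of_baseline <- NA_real_
  key <- interaction(oct$animal_id, oct$region, drop = TRUE)
  for (k in levels(key)) {
    i <- which(key == k)
    bl <- oct$thickness_um[i][oct$day[i] == -1]
    if (length(bl) != 1 || !is.finite(bl) || bl <= 0)
      stopf("missing or invalid day -1 baseline for series %s", k)
    out$percent_of_baseline[i] <- 100 * oct$thickness_um[i] / bl
  }
  out
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "n.s."))))
}

#' Paired t-test of one study day against the day -1 baseline
#'
#' Two-sided paired Student's t-test on per-animal (day - baseline)
#' differences within a region. Zero-variance differences are flagged as
#' degenerate: the p-value is reported as below machine resolution when the
#' mean difference is nonzero, NA when the differences are identically zero.
#'
#' @param oct OCT tibble.
#' @param day the post-baseline study day to test.
#' @param region region to test, default `"central"`.
#' @return One-row tibble: `region`, `day`, `n`, `mean_diff_um`,
#'   `statistic`, `p_value`, `stars`, `degenerate`.
#' @export
paired_test_vs_baseline <- function(oct, day, region = "central") {
  check_oct(oct)
  d <- oct[oct$region == region, ]
  if (!nrow(d)) stopf("no records for region '%s'", region)
  wide <- merge(d[d$day == -1, c("animal_id", "thickness_um")],
                d[d$day == day, c("animal_id", "thickness_um")],
                by = "animal_id", suffixes = c("_bl", "_day"))
  if (nrow(wide) < 2)
    stopf("need >= 2 animals with both baseline and day %s (got %d)",
          day, nrow(wide))
  diffs <- wide$thickness_um_day - wide$thickness_um_bl
  n <- length(diffs)
  if (sd(diffs) == 0) {
    message(sprintf("paired_test_vs_baseline: zero-variance differences at day %s (degenerate)", day))
    p <- if (mean(diffs) != 0) .Machine$double.xmin else NA_real_
    return(tibble(region = region, day = day, n = n,
                  mean_diff_um = mean(diffs), statistic = NA_real_,
                  p_value = p, stars = significance_stars(p),
                  degenerate = TRUE))
  }
  tt <- t.test(wide$thickness_um_day, wide$thickness_um_bl, paired = TRUE)
  tibble(region = region, day = day, n = n, mean_diff_um = mean(diffs),
         statistic = unname(tt$statistic), p_value = tt$p.value,
         stars = significance_stars(tt$p.value), degenerate = FALSE)
}

#' Per-day paired tests for every post-baseline day
#'
#' Convenience wrapper over [paired_test_vs_baseline()]; p-values are
#' reported per day without multiplicity correction (noted in the result's
#' `correction` attribute).
#'
#' @param oct OCT tibble.
#' @param region region to test.
#' @return Tibble with one row per post-baseline day present.
#' @export
oct_day_tests <- function(oct, region = "central") {
  days <- sort(unique(oct$day[oct$region == region & oct$day > -1]))
  out <- do.call(rbind, lapply(days, function(d)
    paired_test_vs_baseline(oct, d, region)))
  attr(out, "correction") <- "none (per-day raw p-values)"
  out
}

#' Peak and residual of the cohort mean swelling curve
#'
#' The peak is the argmax of the across-animal mean thickness over
#' post-injury days (day >= 0), ties broken toward the earlier day. The
#' residual fraction is `(day28 - baseline) / (peak - baseline)`, i.e. the
#' unresolved share of the peak excess at the final day. A peak on the first
#' or last post-injury day is flagged as a boundary (monotone or flat curve).
#'
#' @param oct OCT tibble.
#' @param region region to characterize.
#' @return List of class `oct_peak`: `region`, `peak_day`, `peak_um`,
#'   `baseline_um`, `residual_fraction`, `boundary`.
#' @export
find_peak <- function(oct, region = "central") {
  check_oct(oct)
  d <- oct[oct$region == region, ]
  if (!nrow(d)) stopf("no records for region '%s'", region)
  mean_curve <- tapply(d$thickness_um, d$day, mean)
  days <- as.numeric(names(mean_curve))
  if (length(days) < 3) stopf("need >= 3 time points")
  baseline <- if (any(days == -1)) mean_curve[days == -1] else NA_real_
  post <- days >= 0
  pd <- days[post]; pv <- as.numeric(mean_curve[post])
  i <- which(pv == max(pv))[1]          # ties -> earlier day
  boundary <- i == 1L || i == length(pv)
  if (boundary)
    message(sprintf("find_peak: peak at boundary day %s (monotone or flat curve)", pd[i]))
  last <- as.numeric(mean_curve[which.max(days)])
  resid <- if (!is.na(baseline) && pv[i] != baseline)
    (last - as.numeric(baseline)) / (pv[i] - as.numeric(baseline))
  else NA_real_
  structure(list(region = region, peak_day = pd[i], peak_um = pv[i],
                 baseline_um = as.numeric(baseline),
                 residual_fraction = resid, boundary = boundary),
            class = "oct_peak")
}

#' @export
print.oct_peak <- function(x, ...) {
  cat(sprintf("<oct_peak> %s: peak %.0f um at day %s (baseline %.0f um), residual fraction %.3f%s\n",
              x$region, x$peak_um, x$peak_day, x$baseline_um,
              x$residual_fraction, if (x$boundary) " [boundary]" else ""))
  invisible(x)
}
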