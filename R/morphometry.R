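# Thickness-distribution metrics per eye: z-score standardization, moving
# average smoothing, roughness Ra/Rz, rolling SD, skewness, sigma-exceedance,
# and the per-eye summary feeding the group-comparison table.

#' Standardize a thickness profile to z-scores
#'
#' `z = (thickness - center) / scale`. By default `center`/`scale` are the
#' mean and population SD (divisor n) of `x` itself; pass them explicitly to
#' standardize within a wider scope, e.g. per animal pooling both eyes
#' (the default scope of [summarize_cohort()]). A zero `scale` yields all-zero
#' z-values rather than NaN.
#'
#' @param x numeric thickness values (>= 2) or a measurement tibble.
#' @param center,scale optional standardization parameters (um).
#' @param sd_type `"population"` (divisor n, the z-score convention) or
#'   `"sample"` (divisor n - 1); used only when `scale` is NULL.
#' @return Object of class `standardized_profile`: list with `z`,
#'   `center_um`, `scale_um`.
#' @export
#' @examples
#' standardize(c(1, 2, 3, 4, 5))$z
standardize <- function(x, center = NULL, scale = NULL,
                        sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- profile_values(x)
  if (length(x) < 2) stopf("standardize needs at least 2 samples")
  center <- center %||% mean(x)
  scale <- scale %||% (if (sd_type == "population") sd_pop(x) else sd(x))
  z <- if (scale > 0) (x - center) / scale else rep(0, length(x))
  structure(list(z = z, center_um = center, scale_um = scale),
            class = "standardized_profile")
}

#' @export
print.standardized_profile <- function(x, ...) {
  cat(sprintf("<standardized_profile> n = %d, center = %.4g um, scale = %.4g um\n",
              length(x$z), x$center_um, x$scale_um))
  invisible(x)
}

# accept a numeric vector, a standardized profile, or a measurement tibble
profile_values <- function(x) {
  if (inherits(x, "standardized_profile")) return(x$z)
  if (is.data.frame(x)) {
    if (!"thickness_um" %in% names(x))
      stopf("data frame input must have a thickness_um column")
    return(x$thickness_um)
  }
  as.numeric(x)
}

#' Centered moving-average smoothing
#'
#' Window must be an odd sample count; edge windows shrink symmetrically,
#' `window = 1` is the identity. Intended for profile visualization; metrics
#' are computed on unsmoothed profiles unless explicitly requested.
#'
#' @param x numeric profile.
#' @param window odd positive integer.
#' @return Smoothed numeric vector, same length.
#' @export
smooth_profile <- function(x, window) {
  x <- profile_values(x)
  if (length(window) != 1L || window < 1 || window %% 2 == 0)
    stopf("window must be a single odd positive integer (got %s)",
          paste(window, collapse = ","))
  if (window == 1) return(x)
  n <- length(x)
  h <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1L, n - i)  # shrink symmetrically at the edges
    mean(x[(i - k):(i + k)])
  }, numeric(1))
}

#' Surface roughness Ra and Rz of a standardized profile
#'
#' `Ra` is the arithmetic mean roughness: the mean absolute deviation of the
#' standardized thickness from its mean. `Rz` is the maximum height of the
#' profile: max minus min of the standardized thickness (not the ISO five-peak
#' variant). Both unitless; `Rz >= Ra` always.
#'
#' @param z a [standardize()] result or numeric vector.
#' @return Named numeric vector `c(Ra = , Rz = )`.
#' @export
#' @examples
#' roughness(standardize(c(1, 2, 3, 4, 5)))
roughness <- function(z) {
  z <- profile_values(z)
  if (length(z) < 2) stopf("roughness needs at least 2 samples")
  c(Ra = mean(abs(z - mean(z))), Rz = max(z) - min(z))
}

#' Rolling standard deviation along a profile
#'
#' Sample SD (divisor n - 1) in each full window of `window` consecutive
#' measurements along the linearized contour; the summary is the mean over
#' windows, in the input units (um for raw thickness).
#'
#' @param x numeric profile (length >= `window`).
#' @param window consecutive measurements per window, default 5.
#' @return List of class `rolling_sd`: `values` (length
#'   `length(x) - window + 1`), `mean`, `window`.
#' @export
rolling_sd <- function(x, window = 5) {
  x <- profile_values(x)
  if (length(x) < window)
    stopf("rolling_sd needs at least %d samples (got %d)", window, length(x))
  v <- zoo::rollapply(x, window, sd)
  structure(list(values = v, mean = mean(v), window = window),
            class = "rolling_sd")
}

#' @export
print.rolling_sd <- function(x, ...) {
  cat(sprintf("<rolling_sd> window %d, %d windows, mean %.4g\n",
              x$window, length(x$values), x$mean))
  invisible(x)
}

#' Skewness of a thickness distribution
#'
#' Bias-uncorrected Fisher-Pearson moment coefficient
#' `g1 = m3 / m2^(3/2)` with population moments. Undefined (NA, with a
#' warning) for zero variance.
#'
#' @param x numeric profile (>= 3 samples) or measurement tibble.
#' @return Unitless skewness coefficient.
#' @export
#' @examples
#' profile_skewness(c(0, 0, 0, 0, 10)) # 1.5
profile_skewness <- function(x) {
  x <- profile_values(x)
  if (length(x) < 3) stopf("skewness needs at least 3 samples")
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) {
    warnf("zero variance: skewness undefined, returning NA")
    return(NA_real_)
  }
  mean(d^3) / m2^1.5
}

#' Sigma-exceedance fractions
#'
#' Fraction of standardized measurements with `|z| > k` for each threshold
#' `k` -- a "hot spot" burden metric. Monotone non-increasing in `k`.
#'
#' @param z a [standardize()] result or numeric z-values.
#' @param thresholds numeric thresholds, default `c(1, 2, 3)`.
#' @return Named fractions, e.g. `c(gt1 = , gt2 = , gt3 = )`.
#' @export
exceedance <- function(z, thresholds = c(1, 2, 3)) {
  z <- profile_values(z)
  if (length(z) < 1) stopf("exceedance needs at least 1 sample")
  setNames(vapply(thresholds, function(k) mean(abs(z) > k), numeric(1)),
           paste0("gt", thresholds))
}

#' Morphometry summary for one eye
#'
#' Computes every per-eye metric of the group-comparison table: raw-scale
#' mean/min/max/range and rolling SD; Ra, Rz and sigma-exceedance on the
#' standardized profile; skewness of the raw distribution. Slides are
#' concatenated in slide order to form the linearized contour; set
#' `break_at_slides = TRUE` to keep rolling windows within slides.
#'
#' @param eye_records measurement tibble for a single eye (or a bare numeric
#'   profile).
#' @param center,scale standardization parameters; NULL standardizes within
#'   this eye. [summarize_cohort()] passes per-animal pooled values here.
#' @param rolling_window window for [rolling_sd()], default 5.
#' @param sd_type SD convention for standardization, see [standardize()].
#' @param smooth_window optional odd moving-average window applied to the
#'   profile before all metrics (default 1 = no smoothing).
#' @param break_at_slides compute rolling SD per slide and pool the windows.
#' @return One-row tibble (`morphometry_summary`): `n_measurements`,
#'   `mean_um`, `min_um`, `max_um`, `range_um`, `ra`, `rz`, `skewness`,
#'   `rolling_sd_um`, `frac_exceed_1sd`, `frac_exceed_2sd`, `frac_exceed_3sd`.
#' @export
summarize_eye <- function(eye_records, center = NULL, scale = NULL,
                          rolling_window = 5,
                          sd_type = c("population", "sample"),
                          smooth_window = 1,
                          break_at_slides = FALSE) {
  sd_type <- match.arg(sd_type)
  is_df <- is.data.frame(eye_records)
  if (is_df && nrow(eye_records) == 0) stopf("empty eye series")
  if (is_df)
    eye_records <- eye_records[order(eye_records$slide_id,
                                     eye_records$position_um), ]
  th <- profile_values(eye_records)
  if (length(th) == 0) stopf("empty eye series")
  if (smooth_window > 1) th <- smooth_profile(th, smooth_window)

  z <- standardize(th, center = center, scale = scale, sd_type = sd_type)
  rough <- roughness(z)
  exc <- exceedance(z)

  if (break_at_slides && is_df && "slide_id" %in% names(eye_records)) {
    pieces <- split(th, eye_records$slide_id)
    vals <- unlist(lapply(pieces, function(p)
      if (length(p) >= rolling_window) rolling_sd(p, rolling_window)$values
      else numeric(0)))
    if (!length(vals)) stopf("no slide long enough for rolling window %d",
                             rolling_window)
    rsd <- mean(vals)
  } else {
    rsd <- rolling_sd(th, rolling_window)$mean
  }

  tibble(
    n_measurements = length(th),
    mean_um = mean(th), min_um = min(th), max_um = max(th),
    range_um = max(th) - min(th),
    ra = unname(rough["Ra"]), rz = unname(rough["Rz"]),
    skewness = profile_skewness(th),
    rolling_sd_um = rsd,
    frac_exceed_1sd = unname(exc["gt1"]),
    frac_exceed_2sd = unname(exc["gt2"]),
    frac_exceed_3sd = unname(exc["gt3"])
  )
}

#' Morphometry summaries for a whole cohort
#'
#' One summary row per eye. The standardization scope is `"per_animal"` by
#' default: each animal's mean and population SD are computed pooling both of
#' its eye series and then applied to each eye, removing individual baseline
#' differences while letting an irregular study eye widen that animal's
#' scale. `"per_eye"` standardizes each eye on its own.
#'
#' @param measurements measurement tibble ([read_measurements()] columns).
#' @param scope `"per_animal"` or `"per_eye"`.
#' @inheritParams summarize_eye
#' @return Tibble: `animal_id`, `eye`, `group` plus all [summarize_eye()]
#'   columns.
#' @export
summarize_cohort <- function(measurements,
                             scope = c("per_animal", "per_eye"),
                             rolling_window = 5,
                             sd_type = c("population", "sample"),
                             smooth_window = 1,
                             break_at_slides = FALSE) {
  scope <- match.arg(scope)
  sd_type <- match.arg(sd_type)
  validate_measurements(measurements)
  sdfun <- if (sd_type == "population") sd_pop else sd

  out <- list()
  for (id in unique(measurements$animal_id)) {
    da <- measurements[measurements$animal_id == id, ]
    a_center <- mean(da$thickness_um)
    a_scale <- sdfun(da$thickness_um)
    for (eye in unique(da$eye)) {
      de <- da[da$eye == eye, ]
      row <- if (scope == "per_animal")
        summarize_eye(de, center = a_center, scale = a_scale,
                      rolling_window = rolling_window, sd_type = sd_type,
                      smooth_window = smooth_window,
                      break_at_slides = break_at_slides)
      else
        summarize_eye(de, rolling_window = rolling_window, sd_type = sd_type,
                      smooth_window = smooth_window,
                      break_at_slides = break_at_slides)
      out[[length(out) + 1L]] <- tibble(animal_id = id, eye = eye,
                                        group = de$group[1], row)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$animal_id, res$eye), ]
}
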