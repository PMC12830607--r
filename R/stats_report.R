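# Group comparison (study vs control) and profile visualization: one row per
# metric with means +/- SD per group, the test type, t statistic and raw
# p-value. Paired tests match right (study) and left (control) eyes of the
# same animal; the pooled-measurement thickness row is tested unpaired with
# individual measurements as units.

#' Compare one metric between study and control groups
#'
#' Two-sided t-test of the requested kind: `"paired"` uses animal-matched
#' (study - control) differences, `"unpaired"` a pooled-variance two-sample
#' t-test (Welch via `welch = TRUE`). Zero-variance data are flagged
#' `degenerate` with NA statistic and p-value rather than an error.
#'
#' @param study,control numeric per-eye (or per-measurement) metric values.
#' @param test `"paired"` or `"unpaired"`.
#' @param study_ids,control_ids animal identifiers, required for pairing.
#' @param metric metric name written into the row.
#' @param welch use the Welch (unequal-variance) unpaired test.
#' @return One-row tibble (`group_comparison`): `metric`, `study_mean`,
#'   `study_sd`, `control_mean`, `control_sd`, `n_study`, `n_control`,
#'   `test`, `statistic`, `p_value`, `degenerate`.
#' @export
compare_metric <- function(study, control, test = c("paired", "unpaired"),
                           study_ids = NULL, control_ids = NULL,
                           metric = "metric", welch = FALSE) {
  test <- match.arg(test)
  if (length(study) < 2 || length(control) < 2)
    stopf("need at least 2 values per group")
  base <- tibble(metric = metric,
                 study_mean = mean(study), study_sd = sd(study),
                 control_mean = mean(control), control_sd = sd(control),
                 n_study = length(study), n_control = length(control),
                 test = test, statistic = NA_real_, p_value = NA_real_,
                 degenerate = FALSE)
  if (test == "paired") {
    if (is.null(study_ids) || is.null(control_ids))
      stopf("paired test requires study_ids and control_ids")
    missing <- union(setdiff(study_ids, control_ids),
                     setdiff(control_ids, study_ids))
    if (length(missing))
      stopf("unmatched animal(s) under paired test: %s",
            paste(missing, collapse = ", "))
    o <- order(study_ids); s <- study[o]
    o <- order(control_ids); c_ <- control[o]
    diffs <- s - c_
    if (sd(diffs) == 0) {
      message(sprintf("compare_metric('%s'): zero-variance paired differences (degenerate)",
                      metric))
      base$degenerate <- TRUE
      return(base)
    }
    tt <- t.test(s, c_, paired = TRUE)
  } else {
    if (sd(c(study, control)) == 0) {
      message(sprintf("compare_metric('%s'): both groups constant (degenerate)",
                      metric))
      base$degenerate <- TRUE
      return(base)
    }
    tt <- t.test(study, control, var.equal = !welch)
  }
  base$statistic <- unname(tt$statistic)
  base$p_value <- tt$p.value
  base
}

#' Build the full study-vs-control comparison table
#'
#' One row per metric of the digital-pathology evaluation. Per-eye-averaged
#' metrics ("avg of avgs" thickness, min/max/range, Ra, Rz, exceedance
#' percentages, skewness, rolling SD, measurement counts, cell densities) are
#' tested paired across animals; the pooled "avg total" thickness treats
#' individual measurements as units and is tested unpaired. A metric missing
#' from one group is skipped with a warning.
#'
#' @param summaries per-eye tibble from [summarize_cohort()].
#' @param measurements optional raw measurement tibble; enables the pooled
#'   "Epithelium thickness (avg total)" row.
#' @param densities optional tibble `animal_id`, `group`, `compartment`,
#'   `area_mm2`, `density_per_mm2` (from [cell_density()] per eye).
#' @param welch use Welch for the unpaired row.
#' @return Group-comparison tibble, one row per metric.
#' @export
build_table <- function(summaries, measurements = NULL, densities = NULL,
                        welch = FALSE) {
  stopifnot(all(c("group", "animal_id") %in% names(summaries)))
  s <- summaries[summaries$group == "study", ]
  c_ <- summaries[summaries$group == "control", ]
  if (nrow(s) < 2 || nrow(c_) < 2)
    stopf("need >= 2 eyes per group (got %d study, %d control)",
          nrow(s), nrow(c_))

  paired_row <- function(col, label, scale = 1) {
    if (!col %in% names(summaries)) {
      warnf("metric '%s' missing; row skipped", col)
      return(NULL)
    }
    if (anyNA(s[[col]]) || anyNA(c_[[col]])) {
      warnf("metric '%s' has missing values; row skipped", col)
      return(NULL)
    }
    compare_metric(s[[col]] * scale, c_[[col]] * scale, "paired",
                   study_ids = s$animal_id, control_ids = c_$animal_id,
                   metric = label)
  }

  rows <- list()
  rows$n <- tibble(metric = "Number of samples (n)",
                   study_mean = nrow(s), study_sd = NA_real_,
                   control_mean = nrow(c_), control_sd = NA_real_,
                   n_study = nrow(s), n_control = nrow(c_),
                   test = "none", statistic = NA_real_, p_value = NA_real_,
                   degenerate = FALSE)
  rows$nmeas <- paired_row("n_measurements",
                           "Number of measurements per eye (avg)")
  if (!is.null(measurements)) {
    ms <- measurements$thickness_um[measurements$group == "study"]
    mc <- measurements$thickness_um[measurements$group == "control"]
    rows$avg_total <- compare_metric(ms, mc, "unpaired", welch = welch,
                                     metric = "Epithelium thickness (avg total)")
  }
  rows$avg_avgs <- paired_row("mean_um", "Epithelium thickness (avg of avgs)")
  rows$min <- paired_row("min_um", "Minimal epithelium thickness (avg)")
  rows$max <- paired_row("max_um", "Maximum epithelium thickness (avg)")
  rows$range <- paired_row("range_um", "Max-min difference (avg)")
  rows$ra <- paired_row("ra", "Arithmetic Mean Roughness (Ra)")
  rows$rz <- paired_row("rz", "Maximum Height of Profile (Rz)")
  rows$e1 <- paired_row("frac_exceed_1sd", "Measurements exceeding 1 sigma (%)",
                        scale = 100)
  rows$e2 <- paired_row("frac_exceed_2sd", "Measurements exceeding 2 sigma (%)",
                        scale = 100)
  rows$e3 <- paired_row("frac_exceed_3sd", "Measurements exceeding 3 sigma (%)",
                        scale = 100)
  rows$skew <- paired_row("skewness", "Skewness")
  rows$rsd <- paired_row("rolling_sd_um", "Rolling Standard Deviation")

  if (!is.null(densities)) {
    for (comp in unique(densities$compartment)) {
      dd <- densities[densities$compartment == comp, ]
      ds <- dd[dd$group == "study", ]; dc <- dd[dd$group == "control", ]
      if (nrow(ds) >= 2 && nrow(dc) >= 2) {
        lab <- paste0(tools::toTitleCase(comp), " cell density (avg) - cells/mm^2")
        rows[[paste0("dens_", comp)]] <- compare_metric(
          ds$density_per_mm2, dc$density_per_mm2, "paired",
          study_ids = ds$animal_id, control_ids = dc$animal_id, metric = lab)
        if ("area_mm2" %in% names(dd))
          rows[[paste0("area_", comp)]] <- compare_metric(
            ds$area_mm2, dc$area_mm2, "paired",
            study_ids = ds$animal_id, control_ids = dc$animal_id,
            metric = paste0(tools::toTitleCase(comp),
                            " analyzed area per eye (avg) - mm^2"))
      } else {
        warnf("cell density for '%s' missing in one group; rows skipped", comp)
      }
    }
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Plot per-eye thickness profiles by group
#'
#' Overlaid per-eye profile curves along the linearized contour (slides
#' concatenated), control in blue and study in red, optionally moving-average
#' smoothed and/or z-standardized per animal. Output is deterministic for
#' fixed inputs and configuration.
#'
#' @param measurements measurement tibble.
#' @param path output image file (`.png`, `.pdf`, ...); NULL returns the
#'   ggplot object without writing.
#' @param smooth_window odd moving-average window for display, default 9.
#' @param standardized plot per-animal z-scores instead of micrometres.
#' @param width,height,dpi passed to [ggplot2::ggsave()].
#' @return The output path (or the ggplot object if `path` is NULL),
#'   invisibly.
#' @export
render_profiles <- function(measurements, path, smooth_window = 9,
                            standardized = FALSE,
                            width = 7, height = 4, dpi = 150) {
  validate_measurements(measurements)
  if (nrow(measurements) == 0) stopf("empty measurement input")
  d <- measurements[order(measurements$animal_id, measurements$eye,
                          measurements$slide_id, measurements$position_um), ]
  pieces <- split(d, interaction(d$animal_id, d$eye, drop = TRUE))
  pieces <- lapply(pieces, function(p) {
    dp <- diff(p$position_um)
    step <- if (any(dp > 0)) stats::median(dp[dp > 0]) else 1
    slide_max <- tapply(p$position_um, factor(p$slide_id,
                                              levels = unique(p$slide_id)), max)
    off <- c(0, cumsum(slide_max + step))[seq_along(slide_max)]
    p$linear_um <- p$position_um +
      off[as.integer(factor(p$slide_id, levels = unique(p$slide_id)))]
    val <- p$thickness_um
    if (standardized) {
      zz <- standardize(val)
      val <- zz$z
    }
    if (smooth_window > 1) val <- smooth_profile(val, smooth_window)
    p$value <- val
    p
  })
  d <- do.call(rbind, pieces)
  d$eye_id <- paste(d$animal_id, d$eye)

  gg <- ggplot2::ggplot(d, ggplot2::aes(
    x = linear_um, y = value, group = eye_id, colour = group)) +
    ggplot2::geom_line(linewidth = 0.4, alpha = 0.85) +
    ggplot2::scale_colour_manual(
      values = c(control = "#2166ac", study = "#b2182b")) +
    ggplot2::labs(x = "Position along section (um)",
                  y = if (standardized) "Standardized thickness (z)"
                      else "Epithelial thickness (um)",
                  colour = "Group") +
    ggplot2::theme_minimal(base_size = 10)
  if (is.null(path)) return(invisible(gg))
  ggplot2::ggsave(path, gg, width = width, height = height, dpi = dpi)
  invisible(path)
}
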