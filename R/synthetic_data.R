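# Seeded synthetic cohorts: thickness profiles, labeled histology rasters and
# OCT time series with the statistical structure the downstream analysis
# assumes. Defaults emulate a 4 + 4 eye study: smooth control profiles around
# a ~78 um baseline with small local noise, and study profiles carrying
# localized Gaussian "hot spots" of extreme thinning/thickening.

#' Specification of a synthetic thickness-profile cohort
#'
#' Defaults describe the emulated study: `n_animals` animals, right eye
#' injured (study), left eye intact (control). Each eye profile is
#' `baseline + wander + noise`, where `wander` is a smooth single-period
#' cosine of SD `wander_sd_um` (long-wavelength thickness variation along the
#' section) and `noise` is i.i.d. Gaussian measurement noise. Study eyes
#' additionally carry `hotspot_count` Gaussian bumps (signed amplitudes,
#' width = Gaussian SD in arc length) at uniformly drawn centers.
#'
#' @param n_animals animals per group (paired eyes), default 4.
#' @param baseline_mean_um control epithelial thickness mean, default 77.7 um.
#' @param animal_sd_um between-animal SD of the baseline, default 4 um.
#' @param baseline_sd_um i.i.d. within-profile noise SD, default 4.4 um
#'   (calibrated so control rolling SD matches the study-scale value).
#' @param wander_sd_um SD of the smooth long-wavelength component, default
#'   13 um; set 0 for pure i.i.d. profiles.
#' @param n_points_per_eye named vector `c(study = , control = )` of mean
#'   samples per profile, default c(180, 203).
#' @param n_points_sd between-eye SD of the sample count, default 20.
#' @param spacing_um arc-length step between consecutive measurements, 25 um.
#' @param hotspot_count Gaussian bumps per study eye, default 4.
#' @param hotspot_amplitude_um signed bump amplitudes (recycled), um;
#'   thickening > 0, thinning < 0. Default c(50, -40, 40, -30).
#' @param hotspot_width_um bump width (Gaussian SD), default 150 um.
#' @param floor_um positive clipping floor for thickness, default 5 um.
#' @param region region tag written into the records, default "central".
#' @param seed RNG seed; equal specs + equal seeds give identical output.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals = 4,
                        baseline_mean_um = 77.7,
                        animal_sd_um = 4,
                        baseline_sd_um = 4.4,
                        wander_sd_um = 13,
                        n_points_per_eye = c(study = 180, control = 203),
                        n_points_sd = 20,
                        spacing_um = 25,
                        hotspot_count = 4,
                        hotspot_amplitude_um = c(50, -40, 40, -30),
                        hotspot_width_um = 150,
                        floor_um = 5,
                        region = "central",
                        seed = NULL) {
  if (length(n_points_per_eye) == 1L)
    n_points_per_eye <- c(study = unname(n_points_per_eye),
                          control = unname(n_points_per_eye))
  stopifnot(n_animals >= 1, baseline_mean_um > 0,
            all(n_points_per_eye >= 5), spacing_um > 0,
            hotspot_count >= 0, all(hotspot_width_um > 0), floor_um > 0,
            baseline_sd_um >= 0, wander_sd_um >= 0, animal_sd_um >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_spec> %d animals x 2 eyes; baseline %.1f um (animal SD %.1f),\n",
    "  noise SD %.1f um, wander SD %.1f um, %d hotspot(s) of %s um (width %s um)\n"),
    x$n_animals, x$baseline_mean_um, x$animal_sd_um, x$baseline_sd_um,
    x$wander_sd_um, x$hotspot_count,
    paste(rep_len(x$hotspot_amplitude_um, x$hotspot_count), collapse = "/"),
    paste(unique(rep_len(x$hotspot_width_um, max(1, x$hotspot_count))),
          collapse = "/")))
  invisible(x)
}

# one eye's profile, consuming the current RNG stream
generate_profile_impl <- function(spec, eye_role, animal_id, baseline_um, n) {
  x <- (seq_len(n) - 1) * spec$spacing_um
  L <- max(x)

  w <- rep(0, n)
  if (spec$wander_sd_um > 0) {
    w <- cos(2 * pi * x / L + runif(1, 0, 2 * pi))
    w <- (w - mean(w)) / sd(w) * spec$wander_sd_um
  }
  noise <- if (spec$baseline_sd_um > 0) rnorm(n, 0, spec$baseline_sd_um) else 0

  hotspots <- tibble(center_um = numeric(), amplitude_um = numeric(),
                     width_um = numeric())
  bump <- rep(0, n)
  if (eye_role == "study" && spec$hotspot_count > 0) {
    amp <- rep_len(spec$hotspot_amplitude_um, spec$hotspot_count)
    wid <- rep_len(spec$hotspot_width_um, spec$hotspot_count)
    ctr <- runif(spec$hotspot_count, 0.1 * L, 0.9 * L)
    for (j in seq_len(spec$hotspot_count))
      bump <- bump + amp[j] * exp(-(x - ctr[j])^2 / (2 * wid[j]^2))
    hotspots <- tibble(center_um = ctr, amplitude_um = amp, width_um = wid)
  }

  th <- baseline_um + w + noise + bump
  if (all(th <= spec$floor_um))
    stopf("generated profile is entirely at or below the %.1f um floor; check baseline/amplitudes",
          spec$floor_um)
  th <- pmax(th, spec$floor_um)

  # split into two slide strips, arc length restarting within each slide
  half <- ceiling(n / 2)
  slide <- rep(c("A", "B"), c(half, n - half))
  pos <- x
  pos[slide == "B"] <- x[slide == "B"] - x[half + 1L]

  out <- tibble(
    animal_id = animal_id,
    eye = if (eye_role == "study") "right" else "left",
    group = eye_role,
    region = spec$region,
    slide_id = slide,
    position_um = pos,
    thickness_um = th
  )
  attr(out, "hotspots") <- hotspots
  out
}

#' Generate one synthetic eye profile
#'
#' Control profiles are `baseline + wander + noise`; study profiles
#' additionally carry the spec's Gaussian hot spots. Thickness is clipped at
#' the spec floor. The drawn hot-spot parameters are attached as attribute
#' `"hotspots"`.
#'
#' @param spec a [cohort_spec()].
#' @param eye_role `"study"` or `"control"`.
#' @param animal_id identifier written into the records.
#' @param baseline_um this animal's baseline; default the spec mean.
#' @param n samples; default the spec mean count for the role (no jitter).
#' @param seed optional seed (defaults to `spec$seed`); `NULL` uses the
#'   current RNG state.
#' @return Measurement tibble (see [read_measurements()] for columns).
#' @export
generate_profile <- function(spec, eye_role = c("study", "control"),
                             animal_id = "P1", baseline_um = NULL, n = NULL,
                             seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  eye_role <- match.arg(eye_role)
  baseline_um <- baseline_um %||% spec$baseline_mean_um
  n <- n %||% round(unname(spec$n_points_per_eye[eye_role]))
  run <- function() generate_profile_impl(spec, eye_role, animal_id,
                                          baseline_um, n)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a full synthetic cohort with ground truth
#'
#' `n_animals` paired eyes: study (right) and control (left), each split into
#' slide strips A/B. The ground-truth table records every hot spot drawn
#' (one row per animal x hotspot), for parameter-recovery tests.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional override of `spec$seed`.
#' @return List of class `synthetic_cohort`: `measurements` (tibble),
#'   `ground_truth` (tibble: animal_id, eye, center_um, amplitude_um,
#'   width_um), `spec`, `seed`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_animals < 2)
    warnf("n_animals < 2: paired group tests downstream will not be possible")
  run <- function() {
    meas <- list(); gt <- list()
    for (i in seq_len(spec$n_animals)) {
      id <- sprintf("P%d", i)
      bl <- spec$baseline_mean_um +
        (if (spec$animal_sd_um > 0) rnorm(1, 0, spec$animal_sd_um) else 0)
      for (role in c("study", "control")) {
        n <- max(30L, as.integer(round(
          unname(spec$n_points_per_eye[role]) +
            (if (spec$n_points_sd > 0) rnorm(1, 0, spec$n_points_sd) else 0))))
        p <- generate_profile_impl(spec, role, id, bl, n)
        meas[[length(meas) + 1L]] <- p
        hs <- attr(p, "hotspots")
        if (nrow(hs))
          gt[[length(gt) + 1L]] <- tibble(animal_id = id,
                                          eye = "right", hs)
      }
    }
    list(measurements = do.call(rbind, meas),
         ground_truth = if (length(gt)) do.call(rbind, gt) else
           tibble(animal_id = character(), eye = character(),
                  center_um = numeric(), amplitude_um = numeric(),
                  width_um = numeric()))
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out$measurements <- out$measurements[
    order(out$measurements$animal_id, out$measurements$eye,
          out$measurements$slide_id, out$measurements$position_um), ]
  attr(out$measurements, "hotspots") <- NULL
  out$spec <- spec
  out$seed <- seed
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d measurements, %d eyes, %d ground-truth hotspot(s), seed %s\n",
              nrow(x$measurements),
              nrow(unique(x$measurements[c("animal_id", "eye")])),
              nrow(x$ground_truth),
              if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

# labeled histology rasters --------------------------------------------------

#' Specification of a synthetic labeled histology raster
#'
#' An epithelium band of prescribed local thickness sits on a stroma region
#' (flat or circular-arc basal contour); nuclei are placed by a homogeneous
#' spatial Poisson process at the prescribed density within one compartment
#' and rasterized as disks.
#'
#' @param width_px,height_px raster size in pixels.
#' @param um_per_px calibration, micrometres per pixel.
#' @param geometry `"flat"` or `"arc"`.
#' @param thickness_um epithelial thickness to imprint: scalar or per-column
#'   vector (linearly interpolated to the image width), um.
#' @param band_base_frac row of the (highest point of the) basal contour as a
#'   fraction of image height, default 0.6.
#' @param arc_radius_px basal-contour radius for `geometry = "arc"`.
#' @param nucleus_density_per_mm2 Poisson intensity of nuclei, cells/mm^2.
#' @param nucleus_radius_um rasterized nucleus disk radius, default 3 um.
#' @param nucleus_compartment `"stroma"` or `"epithelium"`.
#' @param avoid_overlap keep nucleus disks disjoint (dart throwing); on
#'   failure falls back to overlapping placement with a warning.
#' @param seed RNG seed.
#' @return Object of class `image_spec`.
#' @export
image_spec <- function(width_px = 600, height_px = 300, um_per_px = 1,
                       geometry = c("flat", "arc"),
                       thickness_um = 80,
                       band_base_frac = 0.6,
                       arc_radius_px = NULL,
                       nucleus_density_per_mm2 = 0,
                       nucleus_radius_um = 3,
                       nucleus_compartment = c("stroma", "epithelium"),
                       avoid_overlap = TRUE,
                       seed = NULL) {
  geometry <- match.arg(geometry)
  nucleus_compartment <- match.arg(nucleus_compartment)
  stopifnot(width_px >= 4, height_px >= 4, um_per_px > 0,
            all(thickness_um > 0), nucleus_density_per_mm2 >= 0,
            nucleus_radius_um > 0)
  if (geometry == "arc" && is.null(arc_radius_px))
    stopf("arc geometry requires arc_radius_px")
  if (max(thickness_um) >= band_base_frac * height_px * um_per_px)
    stopf("imprinted thickness (%.0f um) must be smaller than the space above the basal contour (%.0f um)",
          max(thickness_um), band_base_frac * height_px * um_per_px)
  structure(as.list(environment()), class = "image_spec")
}

#' Generate a synthetic labeled histology image with ground truth
#'
#' @param spec an [image_spec()].
#' @param seed optional override of `spec$seed`.
#' @return List of class `synthetic_image`: `image` (a [labeled_image()]),
#'   `ground_truth` (list: `per_column_thickness_um`, `nucleus_count`,
#'   `nucleus_centers` tibble of pixel row/col), `spec`.
#' @export
generate_histology_image <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "image_spec"))
  run <- function() generate_histology_image_impl(spec)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out$spec <- spec
  class(out) <- "synthetic_image"
  out
}

generate_histology_image_impl <- function(spec) {
  codes <- label_codes()
  H <- spec$height_px; W <- spec$width_px; s <- spec$um_per_px
  labels <- matrix(codes[["background"]], nrow = H, ncol = W)

  # per-column thickness in px
  t_um <- spec$thickness_um
  if (length(t_um) == 1L) t_um <- rep(t_um, W)
  if (length(t_um) != W)
    t_um <- approx(seq(0, 1, length.out = length(t_um)),
                   t_um, seq(0, 1, length.out = W))$y
  t_px <- pmax(1L, as.integer(round(t_um / s)))

  if (spec$geometry == "flat") {
    r_b <- as.integer(round(spec$band_base_frac * H))  # lowest epithelium row
    if (r_b + 1L <= H) labels[(r_b + 1L):H, ] <- codes[["stroma"]]
    for (cc in seq_len(W)) {
      top <- max(1L, r_b - t_px[cc] + 1L)
      labels[top:r_b, cc] <- codes[["epithelium"]]
    }
  } else {
    R <- spec$arc_radius_px
    r_top <- round(spec$band_base_frac * H)
    cy <- r_top + R; cx <- W / 2
    rr <- matrix(seq_len(H), nrow = H, ncol = W)
    ccm <- matrix(seq_len(W), nrow = H, ncol = W, byrow = TRUE)
    d <- sqrt((rr - cy)^2 + (ccm - cx)^2)
    tmat <- matrix(t_px, nrow = H, ncol = W, byrow = TRUE)
    # keep the section within the arc's span: outside these columns the band
    # would run vertically with no stroma beneath it
    span <- abs(ccm - cx) <= 0.9 * R
    labels[span & d <= R] <- codes[["stroma"]]
    labels[span & d > R & d <= R + tmat & rr < cy] <- codes[["epithelium"]]
  }
  true_t_um <- t_px * s

  # nuclei: homogeneous Poisson in the chosen compartment
  comp_code <- codes[[spec$nucleus_compartment]]
  mask_idx <- which(labels == comp_code)
  n_nuc <- 0L
  centers <- tibble(row = integer(), col = integer())
  if (spec$nucleus_density_per_mm2 > 0 && length(mask_idx)) {
    area_mm2 <- length(mask_idx) * s^2 / 1e6
    n_nuc <- stats::rpois(1L, spec$nucleus_density_per_mm2 * area_mm2)
    r_px <- max(1L, as.integer(round(spec$nucleus_radius_um / s)))
    if (spec$nucleus_compartment == "epithelium" &&
        spec$nucleus_radius_um >= min(true_t_um) / 2)
      warnf("nucleus radius >= band thickness / 2: nucleus disks will overlap compartment borders")
    if (n_nuc > 0L) {
      mask <- labels == comp_code
      off <- expand.grid(dr = -r_px:r_px, dc = -r_px:r_px)
      off <- off[off$dr^2 + off$dc^2 <= r_px^2, ]
      disk_inside <- function(r0, c0) {
        rr2 <- r0 + off$dr; cc2 <- c0 + off$dc
        all(rr2 >= 1 & rr2 <= H & cc2 >= 1 & cc2 <= W) &&
          all(mask[cbind(rr2, cc2)])
      }
      pos <- matrix(NA_real_, nrow = 0, ncol = 2)
      attempts <- 0L; max_attempts <- 200L * n_nuc
      min_d2 <- (2 * r_px + 1)^2
      while (nrow(pos) < n_nuc && attempts < max_attempts) {
        attempts <- attempts + 1L
        idx <- mask_idx[sample.int(length(mask_idx), 1L)]
        r0 <- ((idx - 1L) %% H) + 1L
        c0 <- ((idx - 1L) %/% H) + 1L
        if (spec$avoid_overlap &&
            (!disk_inside(r0, c0) ||
               (nrow(pos) &&
                  any((pos[, 1] - r0)^2 + (pos[, 2] - c0)^2 < min_d2)))) next
        pos <- rbind(pos, c(r0, c0))
      }
      if (nrow(pos) < n_nuc) {
        warnf("could not place %d non-overlapping nuclei; placing the remaining %d with overlap allowed",
              n_nuc, n_nuc - nrow(pos))
        extra <- mask_idx[sample.int(length(mask_idx), n_nuc - nrow(pos),
                                     replace = TRUE)]
        pos <- rbind(pos, cbind(((extra - 1L) %% H) + 1L,
                                ((extra - 1L) %/% H) + 1L))
      }
      for (k in seq_len(nrow(pos))) {
        rr2 <- pos[k, 1] + off$dr; cc2 <- pos[k, 2] + off$dc
        ok <- rr2 >= 1 & rr2 <= H & cc2 >= 1 & cc2 <= W
        labels[cbind(rr2[ok], cc2[ok])] <- codes[["nucleus"]]
      }
      centers <- tibble(row = as.integer(pos[, 1]), col = as.integer(pos[, 2]))
    }
  }

  list(image = labeled_image(labels, s),
       ground_truth = list(per_column_thickness_um = true_t_um,
                           nucleus_count = n_nuc,
                           nucleus_centers = centers))
}

# OCT time series ------------------------------------------------------------

#' Specification of synthetic longitudinal OCT pachymetry
#'
#' Corneal thickness per animal/region/day: baseline at day -1, post-injury
#' swelling rising to `peak_multiplier x baseline` at `peak_day` (earlier in
#' the limbus than in the central cornea), then a monotone decline that by
#' day 28 has resolved only `recovery_fraction` of the peak excess, so the
#' series never returns to baseline. Noise is added last.
#'
#' @param baseline_um named per-region baselines, um.
#' @param peak_day named per-region peak days (must be in `days`).
#' @param peak_multiplier named per-region peak/baseline ratio (> 1).
#' @param recovery_fraction fraction of peak excess resolved by day 28,
#'   in (0, 1); default 0.8.
#' @param animal_sd_um between-animal baseline SD, default 25 um.
#' @param noise_sd_um i.i.d. measurement noise SD, default 15 um.
#' @param days acquisition schedule (day -1 = pre-procedure baseline,
#'   0 = immediately post-procedure).
#' @param seed RNG seed.
#' @return Object of class `oct_spec`.
#' @export
oct_spec <- function(baseline_um = c(central = 900, limbal = 800),
                     peak_day = c(central = 8, limbal = 6),
                     peak_multiplier = c(central = 1.6, limbal = 1.4),
                     recovery_fraction = 0.8,
                     animal_sd_um = 25,
                     noise_sd_um = 15,
                     days = c(-1, 0, 5, 6, 7, 8, 9, 10, 11, 17, 23, 28),
                     seed = NULL) {
  regions <- names(baseline_um)
  stopifnot(!is.null(regions), all(baseline_um > 0),
            all(peak_multiplier > 1),
            recovery_fraction > 0, recovery_fraction < 1,
            noise_sd_um >= 0, animal_sd_um >= 0)
  if (!all(peak_day %in% days))
    stopf("peak_day must lie on the acquisition schedule")
  structure(as.list(environment()), class = "oct_spec")
}

oct_curve <- function(day, baseline, peak_day, multiplier, recovery,
                      last_day) {
  excess <- (multiplier - 1) * baseline
  ifelse(day <= peak_day,
         baseline + excess * ((day + 1) / (peak_day + 1))^2,
         baseline + excess * (1 - recovery * (day - peak_day) /
                                (last_day - peak_day)))
}

#' Generate synthetic OCT thickness records
#'
#' @param spec an [oct_spec()].
#' @param n_animals animals, default 4.
#' @param seed optional override of `spec$seed`.
#' @return Tibble: `animal_id`, `region`, `day`, `thickness_um`.
#' @export
generate_oct_series <- function(spec = oct_spec(), n_animals = 4,
                                seed = spec$seed) {
  stopifnot(inherits(spec, "oct_spec"))
  run <- function() {
    out <- list()
    last_day <- max(spec$days)
    for (i in seq_len(n_animals)) {
      shift <- if (spec$animal_sd_um > 0) rnorm(1, 0, spec$animal_sd_um) else 0
      for (reg in names(spec$baseline_um)) {
        bl <- spec$baseline_um[[reg]] + shift
        mu <- oct_curve(spec$days, bl,
                        spec$peak_day[[reg]],
                        spec$peak_multiplier[[reg]],
                        spec$recovery_fraction, last_day)
        th <- mu + (if (spec$noise_sd_um > 0)
          rnorm(length(mu), 0, spec$noise_sd_um) else 0)
        out[[length(out) + 1L]] <- tibble(
          animal_id = sprintf("P%d", i), region = reg,
          day = spec$days, thickness_um = th)
      }
    }
    do.call(rbind, out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
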