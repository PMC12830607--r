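# Derive an ordered epithelial thickness profile from a labeled histology
# raster: trace the stroma/epithelium (basal) interface, then measure the
# epithelium along the local outward normal at regular arc-length steps.
#
# Pixel (r, c) spans x in ((c-1)s, c*s], y in ((r-1)s, r*s] micrometres
# (s = um_per_px, y increasing downward); its centre is ((c-.5)s, (r-.5)s).

#' Extraction configuration
#'
#' @param sampling_step_um spacing of measurement sites along the basal
#'   contour, default 10 um.
#' @param normal_window_um contour smoothing half-width used to estimate
#'   local normals, default 40 um (must be >= `sampling_step_um`).
#' @param min_component_px smallest epithelium connected component retained,
#'   default 50 px.
#' @return Object of class `extraction_config`.
#' @export
extraction_config <- function(sampling_step_um = 10, normal_window_um = 40,
                              min_component_px = 50) {
  stopifnot(sampling_step_um > 0, normal_window_um >= sampling_step_um,
            min_component_px >= 1)
  structure(list(sampling_step_um = sampling_step_um,
                 normal_window_um = normal_window_um,
                 min_component_px = min_component_px),
            class = "extraction_config")
}

#' Extract the basal (stroma/epithelium) contour
#'
#' Returns the lower edge of the epithelium band as a single open polyline
#' ordered by arc length. Epithelium components smaller than
#' `min_component_px` are discarded (reported via message); more than one
#' large component is an error (the section is likely folded).
#'
#' @param image a [labeled_image()].
#' @param config an [extraction_config()].
#' @return Tibble `x_um`, `y_um`, `arc_um` with attribute `um_per_px`.
#' @export
extract_basal_contour <- function(image, config = extraction_config()) {
  stopifnot(inherits(image, "labeled_image"))
  codes <- label_codes()
  epi <- image$labels == codes[["epithelium"]]
  if (!any(epi)) stopf("no epithelium pixels in image")

  comp <- EBImage::bwlabel(epi)
  sizes <- tabulate(comp[comp > 0])
  keep <- which(sizes >= config$min_component_px)
  if (length(keep) == 0L)
    stopf("all %d epithelium component(s) below min_component_px = %d (sizes: %s)",
          length(sizes), config$min_component_px,
          paste(sizes, collapse = ", "))
  if (length(sizes) > length(keep))
    message(sprintf("extract_basal_contour: discarded %d small component(s) (< %d px)",
                    length(sizes) - length(keep), config$min_component_px))
  if (length(keep) > 1L)
    stopf("multiple large disjoint epithelium bands (sizes: %s px); section likely folded",
          paste(sort(sizes[keep], decreasing = TRUE), collapse = ", "))
  band <- comp == keep

  s <- image$um_per_px
  W <- ncol(band)
  pts <- lapply(seq_len(W), function(cc) {
    rr <- which(band[, cc])
    if (!length(rr)) return(NULL)
    # basal edge = lower boundary of the lowest epithelium pixel
    c(x = (cc - 0.5) * s, y = max(rr) * s)
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) < 2) stopf("basal contour degenerate")
  arc <- c(0, cumsum(sqrt(diff(pts[, "x"])^2 + diff(pts[, "y"])^2)))
  out <- tibble(x_um = pts[, "x"], y_um = pts[, "y"], arc_um = arc)
  attr(out, "um_per_px") <- s
  out
}

#' Measure epithelial thickness along basal normals
#'
#' At each arc-length step the epithelium is measured along the outward
#' normal of the smoothed basal contour: the ray is marched in sub-pixel
#' steps and the thickness is the length of the contiguous epithelium run
#' from the basal interface (so keratinized surface irregularities at the
#' outer edge stay included). Rays that leave the image while still inside
#' epithelium yield no sample (gap, reported via message) rather than a
#' truncated zero. Positions are cumulative arc length along the contour.
#'
#' @param image a [labeled_image()] (provides the calibration).
#' @param contour output of [extract_basal_contour()] on the same image.
#' @param config an [extraction_config()].
#' @return Measurement-style tibble `position_um`, `thickness_um`, with
#'   attribute `n_gaps`.
#' @export
measure_thickness <- function(image, contour, config = extraction_config()) {
  stopifnot(inherits(image, "labeled_image"))
  s <- attr(contour, "um_per_px")
  if (is.null(s)) stopf("contour carries no calibration; use extract_basal_contour()")
  if (!isTRUE(all.equal(s, image$um_per_px)))
    stopf("contour calibration (%.4g) does not match image (%.4g)",
          s, image$um_per_px)
  codes <- label_codes()
  lab <- image$labels
  H <- nrow(lab); W <- ncol(lab)
  epi_code <- codes[["epithelium"]]

  arc <- contour$arc_um
  L <- max(arc)
  spacing <- mean(diff(arc))
  samples <- seq(0, L, by = config$sampling_step_um)
  # ray origins on the raw interface
  px <- approx(arc, contour$x_um, samples, rule = 2)$y
  py <- approx(arc, contour$y_um, samples, rule = 2)$y

  # local tangent from a symmetric secant of half-width normal_window_um
  # (symmetric secants are parallel to the true tangent on smooth arcs and
  # average out pixelation); the window shrinks symmetrically near the
  # contour ends, falling back to a short asymmetric secant at the ends
  half <- pmin(config$normal_window_um, samples, L - samples)
  half <- pmax(half, 4 * spacing)
  lo <- pmax(samples - half, 0); hi <- pmin(samples + half, L)
  tx <- approx(arc, contour$x_um, hi, rule = 2)$y -
        approx(arc, contour$x_um, lo, rule = 2)$y
  ty <- approx(arc, contour$y_um, hi, rule = 2)$y -
        approx(arc, contour$y_um, lo, rule = 2)$y
  len <- sqrt(tx^2 + ty^2)
  len[len == 0] <- 1
  nx <- -ty / len; ny <- tx / len  # one of the two normals

  label_at <- function(x, y) {
    cc <- ceiling(x / s); rr <- ceiling(y / s)
    if (is.na(cc) || is.na(rr) || cc < 1 || cc > W || rr < 1 || rr > H)
      return(NA_integer_)
    lab[rr, cc]
  }

  # orient normals toward the epithelium by majority vote over samples
  probe <- 2 * s
  votes <- vapply(seq_along(samples), function(i) {
    a <- label_at(px[i] + probe * nx[i], py[i] + probe * ny[i])
    b <- label_at(px[i] - probe * nx[i], py[i] - probe * ny[i])
    (!is.na(a) && a == epi_code) - (!is.na(b) && b == epi_code)
  }, numeric(1))
  if (sum(votes) < 0) { nx <- -nx; ny <- -ny }

  dt <- 0.25 * s                      # sub-pixel march step, um
  k_max <- ceiling(4 * (H + W))       # ray length cap in steps
  n_gaps <- 0L
  thick <- vapply(seq_along(samples), function(i) {
    hits <- 0L
    for (k in seq_len(k_max)) {
      t_um <- (k - 0.5) * dt          # midpoint sampling avoids edge ties
      l <- label_at(px[i] + t_um * nx[i], py[i] + t_um * ny[i])
      if (is.na(l)) {                 # left the image
        if (hits > 0L) { n_gaps <<- n_gaps + 1L; return(NA_real_) }
        return(NA_real_)
      }
      if (l == epi_code) {
        hits <- hits + 1L
      } else if (hits > 0L) break     # end of the contiguous run
      else break                      # ray starts outside epithelium
    }
    if (hits == 0L) NA_real_ else hits * dt
  }, numeric(1))

  keep <- !is.na(thick)
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(sprintf("measure_thickness: %d of %d sample(s) dropped (%d out-of-bounds gap(s))",
                    dropped, length(samples), n_gaps))
  out <- tibble(position_um = samples[keep], thickness_um = thick[keep])
  attr(out, "n_gaps") <- n_gaps
  out
}
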