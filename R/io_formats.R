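# Measurement CSV, labeled raster and report input/output.
# All unit conventions live here: um for thickness/position, mm^2 for area,
# cells/mm^2 for densities. CSVs are RFC-4180, UTF-8, with a header row.

#' Default column map for measurement CSV files
#'
#' Maps the canonical field names used throughout the package to the column
#' names found in a slide-analysis export. Replace individual entries to adapt
#' to a differently-named export without touching code, e.g.
#' `default_column_map(thickness_um = "Thickness.um")`.
#'
#' @param ... named overrides, `canonical = "file column name"`.
#' @return Named character vector of length 7.
#' @export
#' @examples
#' default_column_map()
#' default_column_map(thickness_um = "thickness")
default_column_map <- function(...) {
  map <- c(
    animal_id    = "animal_id",
    eye          = "eye",
    group        = "group",
    region       = "region",
    slide_id     = "slide_id",
    position_um  = "position_um",
    thickness_um = "thickness_um"
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(map))
    if (length(bad))
      stopf("unknown canonical column(s): %s", paste(bad, collapse = ", "))
    map[names(dots)] <- dots
  }
  map
}

#' Read per-measurement epithelial thickness records
#'
#' Reads a slide-analysis CSV export (one row per thickness measurement) into
#' a validated tibble of measurement records, ordered by
#' (animal, eye, slide, position). Rows with non-positive or non-numeric
#' thickness are rejected with their row numbers reported.
#'
#' @param path CSV file path.
#' @param column_map named character vector from [default_column_map()].
#' @param quiet suppress the row-count message.
#' @return Tibble with columns `animal_id`, `eye` ("right"/"left"), `group`
#'   ("study"/"control"), `region`, `slide_id`, `position_um`, `thickness_um`.
#' @export
read_measurements <- function(path, column_map = default_column_map(),
                              quiet = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(unname(column_map), names(raw))
  if (length(missing))
    stopf("required column(s) missing from %s: %s", path,
          paste(missing, collapse = ", "))
  d <- raw[, unname(column_map)]
  names(d) <- names(column_map)

  th <- suppressWarnings(as.numeric(d$thickness_um))
  bad_parse <- which(is.na(th) & !is.na(d$thickness_um) & d$thickness_um != "")
  if (length(bad_parse))
    stopf("non-numeric thickness at data row(s): %s",
          paste(head(bad_parse, 10L), collapse = ", "))
  d$thickness_um <- th
  d$position_um <- as.numeric(d$position_um)

  bad <- which(is.na(d$thickness_um) | d$thickness_um <= 0)
  if (length(bad))
    stopf("non-positive or missing thickness at data row(s): %s",
          paste(head(bad, 10L), collapse = ", "))

  d <- d[order(d$animal_id, d$eye, d$slide_id, d$position_um), , drop = FALSE]
  rownames(d) <- NULL
  d <- as_tibble(d)
  validate_measurements(d)
  if (!quiet)
    message(sprintf("read_measurements: %d data rows read, %d records kept",
                    nrow(raw), nrow(d)))
  d
}

validate_measurements <- function(d) {
  stopifnot(is.data.frame(d))
  need <- names(default_column_map())
  miss <- setdiff(need, names(d))
  if (length(miss))
    stopf("measurement table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!all(d$eye %in% c("right", "left")))
    stopf("eye must be 'right' (study) or 'left' (control)")
  if (!all(d$group %in% c("study", "control")))
    stopf("group must be 'study' or 'control'")
  ok <- (d$eye == "right") == (d$group == "study")
  if (!all(ok))
    stopf("group inconsistent with eye for %d record(s): right=study, left=control",
          sum(!ok))
  key <- interaction(d$animal_id, d$eye, d$slide_id, drop = TRUE)
  inc <- tapply(d$position_um, key, function(p) all(diff(p) > 0) && all(p >= 0))
  if (!all(unlist(inc)))
    stopf("position_um must be non-negative and strictly increasing within each (animal, eye, slide) series")
  invisible(d)
}

#' Write measurement records to CSV
#'
#' Inverse of [read_measurements()]; the round trip is lossless at full double
#' precision.
#'
#' @param records measurement tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  validate_measurements(records)
  write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# labeled raster images ------------------------------------------------------

#' Integer label codes for histology rasters
#' @return Named integer vector: background 0, stroma 1, epithelium 2,
#'   nucleus 3.
#' @export
label_codes <- function() {
  c(background = 0L, stroma = 1L, epithelium = 2L, nucleus = 3L)
}

#' Construct a calibrated labeled histology image
#'
#' @param labels integer matrix (rows = image rows, top first; 0-based label
#'   codes per [label_codes()]).
#' @param um_per_px physical pixel size, micrometres per pixel (> 0, finite).
#' @return Object of class `labeled_image` with elements `labels`, `um_per_px`.
#' @export
labeled_image <- function(labels, um_per_px) {
  if (!is.matrix(labels)) stopf("labels must be a matrix")
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L ||
      !is.finite(um_per_px) || um_per_px <= 0)
    stopf("um_per_px must be a single finite positive number")
  storage.mode(labels) <- "integer"
  known <- label_codes()
  offending <- setdiff(unique(as.vector(labels)), unname(known))
  if (length(offending))
    stopf("unknown label value(s): %s (allowed: %s)",
          paste(sort(offending), collapse = ", "),
          paste(sprintf("%d=%s", known, names(known)), collapse = ", "))
  structure(list(labels = labels, um_per_px = um_per_px),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  h <- table(factor(as.vector(x$labels), levels = label_codes(),
                    labels = names(label_codes())))
  cat(sprintf("<labeled_image> %d x %d px, %.4g um/px\n",
              nrow(x$labels), ncol(x$labels), x$um_per_px))
  cat("  labels:", paste(sprintf("%s=%d", names(h), h), collapse = ", "), "\n")
  invisible(x)
}

#' Read a labeled histology raster (PNG or TIFF)
#'
#' Single-channel integer labels stored as 8-bit grey values (label value k at
#' grey level k/255). Unknown label values are a format error.
#'
#' @param path PNG or TIFF file.
#' @param um_per_px calibration, micrometres per pixel.
#' @param quiet suppress the label-histogram message.
#' @return A [labeled_image()].
#' @export
read_labeled_image <- function(path, um_per_px, quiet = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported raster format '.%s' (use png or tiff)", ext)
  )
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  labels <- matrix(as.integer(round(px * 255)), nrow = nrow(px))
  img <- labeled_image(labels, um_per_px)
  if (!quiet) {
    h <- table(as.vector(labels))
    message(sprintf("read_labeled_image: %d x %d px; labels {%s}",
                    nrow(labels), ncol(labels),
                    paste(sprintf("%s:%d", names(h), h), collapse = ", ")))
  }
  img
}

#' Write a labeled histology raster (PNG or TIFF)
#'
#' @param image a [labeled_image()].
#' @param path destination (`.png`, `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_labeled_image <- function(image, path) {
  stopifnot(inherits(image, "labeled_image"))
  grey <- image$labels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(grey, path),
    tif  = ,
    tiff = tiff::writeTIFF(grey, path, bits.per.sample = 8L),
    stopf("unsupported raster format '.%s' (use png or tiff)", ext)
  )
  invisible(path)
}

# group-comparison reports ---------------------------------------------------

#' Write a group-comparison report
#'
#' Machine-readable CSV (one row per metric: group means, SDs, n, test type,
#' t statistic, p-value). Values are written at full double precision so that
#' [read_report()] reproduces them bit-for-bit.
#'
#' @param comparisons group-comparison tibble from [build_table()] or
#'   [compare_metric()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(comparisons, path) {
  if (!is.data.frame(comparisons) || nrow(comparisons) == 0L)
    stopf("comparisons must be a non-empty data frame")
  out <- as.data.frame(comparisons)
  num <- vapply(out, is.numeric, logical(1))
  # full 17 significant digits keeps the write -> read round trip exact
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a group-comparison report written by [write_report()]
#' @param path report CSV path.
#' @return Tibble with the same columns and values.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  numcols <- intersect(
    c("study_mean", "study_sd", "control_mean", "control_sd",
      "n_study", "n_control", "statistic", "p_value"),
    names(d))
  d[numcols] <- lapply(d[numcols], as.numeric)
  if ("degenerate" %in% names(d)) d$degenerate <- as.logical(d$degenerate)
  as_tibble(d)
}
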