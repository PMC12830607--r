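# Stage runner tying the modules into a reproducible pipeline. Every run
# writes the fully resolved configuration (YAML) and a log file into the
# output directory, so an analysis can be audited and re-run byte-for-byte.

#' Assemble and validate a pipeline configuration
#'
#' Any entry may be overridden; the resolved configuration (defaults merged
#' with overrides) is serialized into every output directory.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed used for every stochastic stage.
#' @param column_map measurement CSV column map, see [default_column_map()].
#' @param cohort a [cohort_spec()] for the `simulate` stage.
#' @param image an [image_spec()] for the `simulate`/`extract` stages.
#' @param oct an [oct_spec()] for the `simulate`/`oct` stages.
#' @param extraction an [extraction_config()].
#' @param scope standardization scope for [summarize_cohort()].
#' @param rolling_window rolling-SD window.
#' @param smooth_window display smoothing window for the profile figure.
#' @param measurements_csv optional path to an existing measurement CSV; when
#'   given, analysis stages read it instead of the simulated cohort.
#' @param log_level `"info"` or `"quiet"`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("epimorph_run_"),
                            seed = 1L,
                            column_map = default_column_map(),
                            cohort = cohort_spec(),
                            image = image_spec(nucleus_density_per_mm2 = 1082,
                                               seed = NULL),
                            oct = oct_spec(),
                            extraction = extraction_config(),
                            scope = "per_animal",
                            rolling_window = 5,
                            smooth_window = 9,
                            measurements_csv = NULL,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(inherits(cohort, "cohort_spec"), inherits(image, "image_spec"),
            inherits(oct, "oct_spec"), inherits(extraction, "extraction_config"),
            is.numeric(seed), length(seed) == 1L)
  scope <- match.arg(scope, c("per_animal", "per_eye"))
  if (!is.null(measurements_csv) && !file.exists(measurements_csv))
    stopf("measurements_csv does not exist: %s", measurements_csv)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 column_map = column_map, cohort = cohort, image = image,
                 oct = oct, extraction = extraction, scope = scope,
                 rolling_window = rolling_window,
                 smooth_window = smooth_window,
                 measurements_csv = measurements_csv,
                 log_level = log_level),
            class = "pipeline_config")
}

pipeline_log <- function(config, ...) {
  line <- sprintf(...)
  cat(line, "\n", file = file.path(config$outdir, "run.log"),
      append = TRUE, sep = "")
  if (config$log_level == "info") message(line)
  invisible(line)
}

config_as_list <- function(x) {
  if (inherits(x, c("pipeline_config", "cohort_spec", "image_spec",
                    "oct_spec", "extraction_config")))
    return(lapply(unclass(x), config_as_list))
  x
}

#' Run pipeline stages
#'
#' Stages: `simulate` (synthetic cohort CSV + ground truth + labeled raster +
#' OCT series), `extract` (raster to thickness profile), `morphometry`
#' (per-eye summaries), `cellularity` (compartment densities), `oct`
#' (percent-of-baseline, per-day paired tests, peak), `report`
#' (group-comparison table + profile figure), or `all` in dependency order.
#' Analysis stages consume the artifacts of `simulate` in `outdir` unless
#' `measurements_csv` points at existing data. Inputs are never mutated; a
#' rerun with the same config and seed into a clean directory reproduces
#' every numeric artifact byte-for-byte.
#'
#' @param stage one of `"simulate"`, `"extract"`, `"morphometry"`,
#'   `"cellularity"`, `"oct"`, `"report"`, `"all"`.
#' @param config a [pipeline_config()].
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "extract",
                                   "morphometry", "cellularity", "oct",
                                   "report"),
                         config = pipeline_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config_as_list(config),
                   file.path(config$outdir, "config.yaml"))
  pipeline_log(config, "[%s] stage '%s' starting (seed %d)",
               "epimorph", stage, config$seed)

  stages <- if (stage == "all")
    c("simulate", "extract", "morphometry", "cellularity", "oct", "report")
  else stage
  artifacts <- list()
  for (st in stages) {
    artifacts <- c(artifacts, switch(st,
      simulate    = stage_simulate(config),
      extract     = stage_extract(config),
      morphometry = stage_morphometry(config),
      cellularity = stage_cellularity(config),
      oct         = stage_oct(config),
      report      = stage_report(config)))
    pipeline_log(config, "stage '%s' done", st)
  }
  invisible(artifacts)
}

path_in <- function(config, name) file.path(config$outdir, name)

stage_simulate <- function(config) {
  co <- generate_cohort(config$cohort, seed = config$seed)
  write_measurements(co$measurements, path_in(config, "measurements.csv"))
  write.csv(co$ground_truth, path_in(config, "ground_truth.csv"),
            row.names = FALSE)
  img <- generate_histology_image(config$image, seed = config$seed + 1L)
  write_labeled_image(img$image, path_in(config, "histology_labels.png"))
  jsonlite::write_json(
    list(nucleus_count = img$ground_truth$nucleus_count,
         per_column_thickness_um = img$ground_truth$per_column_thickness_um),
    path_in(config, "histology_ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  oct <- generate_oct_series(config$oct, seed = config$seed + 2L)
  write.csv(oct, path_in(config, "oct_series.csv"), row.names = FALSE)
  pipeline_log(config, "simulate: %d measurements, %d nuclei, %d OCT records",
               nrow(co$measurements), img$ground_truth$nucleus_count,
               nrow(oct))
  list(measurements = path_in(config, "measurements.csv"),
       ground_truth = path_in(config, "ground_truth.csv"),
       histology = path_in(config, "histology_labels.png"),
       oct = path_in(config, "oct_series.csv"))
}

stage_extract <- function(config) {
  img_path <- path_in(config, "histology_labels.png")
  if (!file.exists(img_path))
    stopf("stage 'extract': %s missing (run 'simulate' first)", img_path)
  img <- read_labeled_image(img_path, config$image$um_per_px, quiet = TRUE)
  contour <- extract_basal_contour(img, config$extraction)
  prof <- measure_thickness(img, contour, config$extraction)
  write.csv(prof, path_in(config, "extracted_profile.csv"), row.names = FALSE)
  pipeline_log(config, "extract: %d thickness samples", nrow(prof))
  list(extracted_profile = path_in(config, "extracted_profile.csv"))
}

read_stage_measurements <- function(config) {
  src <- config$measurements_csv %||% path_in(config, "measurements.csv")
  if (!file.exists(src))
    stopf("measurement CSV %s missing (run 'simulate' first or set measurements_csv)",
          src)
  read_measurements(src, config$column_map, quiet = TRUE)
}

stage_morphometry <- function(config) {
  meas <- read_stage_measurements(config)
  summ <- summarize_cohort(meas, scope = config$scope,
                           rolling_window = config$rolling_window)
  write.csv(summ, path_in(config, "morphometry_summaries.csv"),
            row.names = FALSE)
  pipeline_log(config, "morphometry: %d eye summaries (%s scope)",
               nrow(summ), config$scope)
  list(summaries = path_in(config, "morphometry_summaries.csv"))
}

stage_cellularity <- function(config) {
  img_path <- path_in(config, "histology_labels.png")
  if (!file.exists(img_path))
    stopf("stage 'cellularity': %s missing (run 'simulate' first)", img_path)
  img <- read_labeled_image(img_path, config$image$um_per_px, quiet = TRUE)
  dens <- rbind(cell_density(img, "stroma"),
                if (any(img$labels == label_codes()[["epithelium"]]))
                  cell_density(img, "epithelium"))
  write.csv(dens, path_in(config, "cell_density.csv"), row.names = FALSE)
  pipeline_log(config, "cellularity: %s",
               paste(sprintf("%s %.0f/mm^2", dens$compartment,
                             dens$density_per_mm2), collapse = ", "))
  list(cell_density = path_in(config, "cell_density.csv"))
}

stage_oct <- function(config) {
  oct_path <- path_in(config, "oct_series.csv")
  if (!file.exists(oct_path))
    stopf("stage 'oct': %s missing (run 'simulate' first)", oct_path)
  oct <- as_tibble(read.csv(oct_path, stringsAsFactors = FALSE))
  pct <- percent_of_baseline(oct)
  write.csv(pct, path_in(config, "oct_percent_of_baseline.csv"),
            row.names = FALSE)
  tests <- do.call(rbind, lapply(unique(oct$region),
                                 function(r) oct_day_tests(oct, r)))
  write.csv(tests, path_in(config, "oct_day_tests.csv"), row.names = FALSE)
  peaks <- lapply(unique(oct$region), function(r) {
    pk <- find_peak(oct, r)
    pk[c("region", "peak_day", "peak_um", "baseline_um",
         "residual_fraction", "boundary")]
  })
  jsonlite::write_json(peaks, path_in(config, "oct_peaks.json"),
                       auto_unbox = TRUE, digits = NA)
  pipeline_log(config, "oct: %d day tests across %d region(s)",
               nrow(tests), length(unique(oct$region)))
  list(oct_percent = path_in(config, "oct_percent_of_baseline.csv"),
       oct_tests = path_in(config, "oct_day_tests.csv"),
       oct_peaks = path_in(config, "oct_peaks.json"))
}

stage_report <- function(config) {
  meas <- read_stage_measurements(config)
  summ <- summarize_cohort(meas, scope = config$scope,
                           rolling_window = config$rolling_window)
  table <- build_table(summ, measurements = meas)
  write_report(table, path_in(config, "group_comparison.csv"))
  render_profiles(meas, path_in(config, "thickness_profiles.png"),
                  smooth_window = config$smooth_window)
  pipeline_log(config, "report: %d metric rows", nrow(table))
  list(report = path_in(config, "group_comparison.csv"),
       figure = path_in(config, "thickness_profiles.png"))
}
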