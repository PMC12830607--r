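# Group comparisons against textbook closed forms, table construction
# invariances, and deterministic profile rendering.

test_that("paired and unpaired t-tests match textbook closed forms", {
  # identical groups with internal spread: t = 0, p = 1
  r0 <- compare_metric(c(1, 2, 3, 4), c(1, 2, 3, 4), "unpaired")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # constant paired differences: degenerate flag, no p-value
  expect_message(
    rd <- compare_metric(c(2, 4, 6, 8), c(1, 3, 5, 7), "paired",
                         study_ids = sprintf("P%d", 1:4),
                         control_ids = sprintf("P%d", 1:4)),
    "degenerate")
  expect_true(rd$degenerate)
  expect_true(is.na(rd$p_value))

  # paired differences [1,2,3,4]: t = 2.5 / (1.29099/2) = 3.873, p = 0.0305
  rp <- compare_metric(c(10, 12, 14, 16), c(9, 10, 11, 12), "paired",
                       study_ids = sprintf("P%d", 1:4),
                       control_ids = sprintf("P%d", 1:4))
  d <- c(1, 2, 3, 4)
  t_closed <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(rp$statistic, t_closed, tolerance = 1e-6)
  expect_equal(rp$p_value, 2 * pt(-abs(t_closed), df = 3), tolerance = 1e-6)

  # unpaired pooled-variance closed form on a hand-worked 4+4 example
  s <- c(10, 12, 14, 16); c_ <- c(9, 10, 11, 12)
  ru <- compare_metric(s, c_, "unpaired")
  sp2 <- (3 * var(s) + 3 * var(c_)) / 6
  t_u <- (mean(s) - mean(c_)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(ru$statistic, t_u, tolerance = 1e-6)
  expect_equal(ru$p_value, 2 * pt(-abs(t_u), df = 6), tolerance = 1e-6)

  # unmatched animals under pairing: error naming the missing pair
  expect_error(
    compare_metric(1:3, 1:3, "paired", study_ids = c("P1", "P2", "P3"),
                   control_ids = c("P1", "P2", "P4")),
    "P3|P4")
})

test_that("build_table produces one row per metric with the right tests", {
  co <- generate_cohort(cohort_spec(seed = 11))
  summ <- summarize_cohort(co$measurements)
  tab <- build_table(summ, measurements = co$measurements)

  expect_equal(anyDuplicated(tab$metric), 0)
  expect_equal(tab$study_mean[tab$metric == "Number of samples (n)"], 4)
  expect_equal(tab$control_mean[tab$metric == "Number of samples (n)"], 4)
  pooled <- tab[tab$metric == "Epithelium thickness (avg total)", ]
  expect_equal(pooled$test, "unpaired")
  expect_equal(pooled$n_study,
               sum(co$measurements$group == "study"))
  expect_true(all(tab$test[tab$metric %in%
                             c("Maximum Height of Profile (Rz)",
                               "Skewness")] == "paired"))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1, na.rm = TRUE))
  expect_true(all(tab$study_sd >= 0, na.rm = TRUE))

  # row count invariant to input ordering; values invariant to relabeling
  perm <- summ[sample(nrow(summ)), ]
  tab2 <- build_table(perm, measurements = co$measurements)
  expect_equal(nrow(tab2), nrow(tab))
  expect_equal(tab2[order(tab2$metric), ]$p_value,
               tab[order(tab$metric), ]$p_value, tolerance = 1e-12)

  relab <- summ
  relab$animal_id <- sub("P", "Animal-", relab$animal_id)
  tab3 <- build_table(relab)
  common <- intersect(tab$metric, tab3$metric)
  expect_equal(tab3$p_value[match(common, tab3$metric)],
               tab$p_value[match(common, tab$metric)], tolerance = 1e-12)
})

test_that("cell-density rows join the table when provided", {
  co <- generate_cohort(cohort_spec(seed = 12))
  summ <- summarize_cohort(co$measurements)
  dens <- tibble::tibble(
    animal_id = rep(sprintf("P%d", 1:4), 2),
    group = rep(c("study", "control"), each = 4),
    compartment = "stroma",
    area_mm2 = runif(8, 5, 7),
    density_per_mm2 = c(rnorm(4, 2534, 300), rnorm(4, 1082, 150)))
  tab <- build_table(summ, densities = dens)
  row <- tab[grepl("Stroma cell density", tab$metric), ]
  expect_equal(nrow(row), 1)
  expect_equal(row$test, "paired")
  expect_gt(row$study_mean, row$control_mean)
})

test_that("profile rendering is deterministic and shows group separation", {
  co <- generate_cohort(cohort_spec(seed = 13))
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_profiles(co$measurements, f1)
  expect_gt(file.info(f1)$size, 0)
  render_profiles(co$measurements, f2)
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
                   readBin(f2, "raw", file.info(f2)$size))

  # with hotspots well above noise the plotted study range exceeds control
  gg <- render_profiles(co$measurements, NULL, smooth_window = 1)
  d <- gg$data
  rng <- tapply(d$value, d$group, function(v) max(v) - min(v))
  expect_gt(rng[["study"]], rng[["control"]])

  expect_error(render_profiles(co$measurements[0, ], f1))
})
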