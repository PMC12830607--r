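# Synthetic generators: determinism, exactness of noise-free output,
# analytic bump structure, Poisson nucleus counts, OCT curve arithmetic.

noise_free_spec <- function(...) {
  cohort_spec(baseline_sd_um = 0, wander_sd_um = 0, animal_sd_um = 0,
              n_points_sd = 0, ...)
}

test_that("noise-free, hotspot-free profiles are exactly the baseline", {
  sp <- noise_free_spec(hotspot_count = 0, baseline_mean_um = 80, seed = 1)
  p <- generate_profile(sp, "study", n = 100)
  expect_equal(nrow(p), 100)
  expect_true(all(p$thickness_um == 80))
  expect_true(all(p$group == "study" & p$eye == "right"))
  # positions strictly increasing within each slide
  for (sl in unique(p$slide_id))
    expect_true(all(diff(p$position_um[p$slide_id == sl]) > 0))
})

test_that("generation is deterministic under a fixed seed", {
  sp <- cohort_spec(seed = 123)
  expect_identical(generate_profile(sp, "study"), generate_profile(sp, "study"))
  c1 <- generate_cohort(sp); c2 <- generate_cohort(sp)
  expect_identical(c1$measurements, c2$measurements)
  expect_identical(c1$ground_truth, c2$ground_truth)
  # different seed, different draw
  expect_false(identical(
    c1$measurements$thickness_um,
    generate_cohort(cohort_spec(seed = 124))$measurements$thickness_um))

  im <- image_spec(width_px = 60, height_px = 50, thickness_um = 20,
                   nucleus_density_per_mm2 = 5e3, nucleus_radius_um = 1.5,
                   seed = 9)
  expect_identical(generate_histology_image(im)$image$labels,
                   generate_histology_image(im)$image$labels)
  oc <- oct_spec(seed = 4)
  expect_identical(generate_oct_series(oc), generate_oct_series(oc))
})

test_that("a single noise-free bump gives range equal to its amplitude", {
  sp <- noise_free_spec(hotspot_count = 1, hotspot_amplitude_um = 40,
                        baseline_mean_um = 80, seed = 6)
  p <- generate_profile(sp, "study", n = 200)
  r <- max(p$thickness_um) - min(p$thickness_um)
  expect_equal(r, 40, tolerance = 0.01)  # peak sampling, 1 %
  # analytic check at the recorded center
  hs <- attr(p, "hotspots")
  expect_equal(nrow(hs), 1)
  x <- c(p$position_um[p$slide_id == "A"],
         p$position_um[p$slide_id == "B"] + max(p$position_um[p$slide_id == "A"]) + sp$spacing_um)
  expected <- 80 + 40 * exp(-(x - hs$center_um)^2 / (2 * hs$width_um^2))
  expect_equal(p$thickness_um, expected, tolerance = 1e-9)
})

test_that("increasing hotspot amplitude never shrinks the noise-free range", {
  ranges <- vapply(c(0, 10, 20, 40, 60), function(a) {
    sp <- noise_free_spec(hotspot_count = 1, hotspot_amplitude_um = a,
                          seed = 17)
    p <- generate_profile(sp, "study", n = 150)
    max(p$thickness_um) - min(p$thickness_um)
  }, numeric(1))
  expect_true(all(diff(ranges) >= 0))
})

test_that("cohorts have the configured structure and ground truth", {
  co <- generate_cohort(cohort_spec(n_animals = 4, seed = 2))
  eyes <- unique(co$measurements[c("animal_id", "eye")])
  expect_equal(nrow(eyes), 8)
  expect_equal(sort(unique(co$measurements$group)), c("control", "study"))
  expect_equal(nrow(co$ground_truth), 4 * 4)  # animals x hotspot_count
  # both slides present per eye
  expect_true(all(tapply(co$measurements$slide_id,
                         interaction(co$measurements$animal_id,
                                     co$measurements$eye),
                         function(s) all(c("A", "B") %in% s))))
  expect_warning(generate_cohort(cohort_spec(n_animals = 1, seed = 1)),
                 "paired")
})

test_that("profiles entirely below the floor are a generation error", {
  sp <- noise_free_spec(hotspot_count = 0, baseline_mean_um = 3, seed = 1)
  expect_error(generate_profile(sp, "control", n = 50), "floor")
})

test_that("flat histology band is exactly the imprinted thickness", {
  sp <- image_spec(width_px = 120, height_px = 150, um_per_px = 1,
                   thickness_um = 80, seed = 1)
  gen <- generate_histology_image(sp)
  cols <- colSums(gen$image$labels == label_codes()[["epithelium"]])
  expect_true(all(cols == 80))
  expect_true(all(gen$ground_truth$per_column_thickness_um == 80))
  # density 0 -> zero nucleus pixels
  expect_equal(sum(gen$image$labels == label_codes()[["nucleus"]]), 0)
})

test_that("nucleus ground-truth counts follow the Poisson law", {
  # modest raster so 25 seeded replicates stay quick; stroma area is
  # (height - basal row) x width px
  sp0 <- image_spec(width_px = 250, height_px = 220, thickness_um = 40,
                    nucleus_density_per_mm2 = 1082, nucleus_radius_um = 3,
                    seed = 1)
  area_mm2 <- (220 - round(0.6 * 220)) * 250 / 1e6
  lambda <- 1082 * area_mm2
  counts <- vapply(1:25, function(s)
    generate_histology_image(sp0, seed = s)$ground_truth$nucleus_count,
    numeric(1))
  se <- sqrt(lambda / 25)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("OCT series follow the prescribed rise/peak/recovery curve", {
  sp <- oct_spec(baseline_um = c(central = 800), peak_day = c(central = 8),
                 peak_multiplier = c(central = 1.5), recovery_fraction = 0.8,
                 noise_sd_um = 0, animal_sd_um = 0, seed = 1)
  oc <- generate_oct_series(sp, n_animals = 1)
  expect_equal(oc$thickness_um[oc$day == -1], 800)
  expect_equal(oc$thickness_um[oc$day == 8], 1200)
  expect_equal(oc$thickness_um[oc$day == 28], 880)  # baseline + 0.2 * excess
  # strictly increasing before the peak, strictly decreasing after
  pre <- oc$thickness_um[oc$day <= 8]
  post <- oc$thickness_um[oc$day >= 8]
  expect_true(all(diff(pre) > 0))
  expect_true(all(diff(post) < 0))
})
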