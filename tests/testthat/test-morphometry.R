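# Thickness-distribution metrics: hand-derived examples, analytic
# expectations, and equivalence with independent naive oracles.

test_that("standardization matches hand computation and handles degenerate scale", {
  z <- standardize(c(1, 2, 3, 4, 5))
  expect_equal(z$center_um, 3)
  expect_equal(z$scale_um, sqrt(2))
  expect_equal(z$z, c(-1.4142, -0.7071, 0, 0.7071, 1.4142), tolerance = 1e-4)
  expect_equal(mean(z$z), 0, tolerance = 1e-9)
  expect_equal(sd_z <- sqrt(mean(z$z^2)), 1, tolerance = 1e-9)

  # zero variance -> all zeros, not NaN
  zc <- standardize(rep(80, 10))
  expect_true(all(zc$z == 0))

  # idempotence: standardizing an already-standardized profile is identity
  z2 <- standardize(z$z)
  expect_equal(z2$z, z$z, tolerance = 1e-12)

  expect_error(standardize(numeric(0)), "at least 2")
})

test_that("moving-average smoothing is centered with shrunken edges", {
  expect_identical(smooth_profile(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  expect_equal(smooth_profile(c(0, 10, 0, 10, 0), 5)[3], 4)
  expect_equal(smooth_profile(rep(7, 20), 9), rep(7, 20))
  expect_error(smooth_profile(1:10, 4), "odd")
  # edge windows shrink symmetrically -> agree with oracle
  set.seed(11)
  x <- rnorm(31)
  for (w in c(3, 5, 9)) expect_equal(smooth_profile(x, w), oracle_smooth(x, w))
})

test_that("Ra and Rz match hand-derived values and analytic expectation", {
  expect_equal(unname(roughness(rep(0, 10))), c(0, 0))
  z <- standardize(c(1, 2, 3, 4, 5))
  r <- roughness(z)
  expect_equal(unname(r["Ra"]), 0.8485, tolerance = 1e-4)
  expect_equal(unname(r["Rz"]), 2.8284, tolerance = 1e-4)

  # E|Z| = sqrt(2/pi) for standard normal z
  set.seed(42)
  zn <- rnorm(1e5)
  expect_equal(unname(roughness(zn)["Ra"]), sqrt(2 / pi), tolerance = 0.01)
})

test_that("rolling SD uses sample SD in full windows", {
  expect_true(all(rolling_sd(rep(80, 30))$values == 0))
  r <- rolling_sd(c(0, 1, 0, 1, 0), 5)
  expect_length(r$values, 1)
  expect_equal(r$values, 0.5477, tolerance = 1e-4)
  expect_error(rolling_sd(1:3, 5), "at least 5")

  # a localized bump strictly raises the summary over the flat profile
  flat <- rep(80, 100)
  bumped <- flat + 40 * exp(-((1:100) - 50)^2 / (2 * 3^2))
  expect_gt(rolling_sd(bumped)$mean, rolling_sd(flat)$mean)
})

test_that("skewness is the bias-uncorrected moment coefficient g1", {
  expect_equal(profile_skewness(c(1, 2, 3, 4, 5)), 0)
  expect_equal(profile_skewness(c(0, 0, 0, 0, 10)), 1.5)
  set.seed(3)
  x <- rexp(50)
  expect_equal(profile_skewness(-x), -profile_skewness(x))
  expect_warning(s <- profile_skewness(rep(2, 5)), "zero variance")
  expect_true(is.na(s))
})

test_that("sigma-exceedance fractions match counts and Gaussian tails", {
  expect_equal(unname(exceedance(rep(0, 5))), c(0, 0, 0))
  z <- standardize(c(1, 2, 3, 4, 5))
  expect_equal(unname(exceedance(z)), c(0.4, 0, 0))
  set.seed(7)
  zn <- rnorm(1e5)
  e <- exceedance(zn)
  expect_equal(unname(e), c(0.3173, 0.0455, 0.0027), tolerance = 0.05)
  # monotone non-increasing in the threshold
  expect_true(all(diff(unname(e)) <= 0))
})

test_that("summarize_eye computes every metric and satisfies its invariants", {
  const <- make_eye_records(rep(80, 100))
  expect_warning(s <- summarize_eye(const), "zero variance")  # skewness NA
  expect_equal(s$mean_um, 80)
  expect_equal(s$min_um, 80)
  expect_equal(s$max_um, 80)
  expect_equal(s$range_um, 0)
  expect_equal(s$ra, 0)
  expect_equal(s$rz, 0)
  expect_equal(s$frac_exceed_1sd + s$frac_exceed_2sd + s$frac_exceed_3sd, 0)

  # invariants on random profiles
  set.seed(21)
  for (i in 1:25) {
    x <- 60 + rnorm(sample(5:300, 1), 0, runif(1, 0.5, 20))
    s <- summarize_eye(make_eye_records(pmax(x, 1)))
    expect_lte(s$min_um, s$mean_um)
    expect_lte(s$mean_um, s$max_um)
    expect_equal(s$range_um, s$max_um - s$min_um)
    expect_gte(s$ra, 0)
    expect_gte(s$rz, s$ra)
    expect_true(1 >= s$frac_exceed_1sd &&
                  s$frac_exceed_1sd >= s$frac_exceed_2sd &&
                  s$frac_exceed_2sd >= s$frac_exceed_3sd &&
                  s$frac_exceed_3sd >= 0)
  }
})

test_that("every metric equals its independent oracle on random profiles", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(5:500, 1)
    x <- 60 + rnorm(n, 0, runif(1, 0.5, 25))
    z <- standardize(x)

    expect_equal(z$z, oracle_z(x), tolerance = 1e-9)
    r <- roughness(z)
    expect_equal(unname(r["Ra"]), oracle_ra(oracle_z(x)), tolerance = 1e-9)
    expect_equal(unname(r["Rz"]), oracle_rz(oracle_z(x)), tolerance = 1e-9)
    expect_equal(rolling_sd(x)$values, oracle_rolling_sd(x), tolerance = 1e-9)
    expect_equal(profile_skewness(x), oracle_skew(x), tolerance = 1e-9)
    for (k in 1:3)
      expect_equal(unname(exceedance(z, k)), oracle_exceed(oracle_z(x), k),
                   tolerance = 1e-9)
  }
})

test_that("scale- and shift-invariance of the standardized metrics", {
  set.seed(5)
  x <- 70 + rnorm(120, 0, 8)
  a <- 2.7; b <- 13
  y <- a * x + b
  zx <- standardize(x); zy <- standardize(y)
  expect_equal(roughness(zx), roughness(zy), tolerance = 1e-9)
  expect_equal(exceedance(zx), exceedance(zy), tolerance = 1e-12)
  expect_equal(profile_skewness(x), profile_skewness(y), tolerance = 1e-9)
})

test_that("per-animal scope pools both eyes of one animal", {
  set.seed(8)
  right <- make_eye_records(80 + rnorm(50, 0, 10), eye = "right")
  left <- make_eye_records(80 + rnorm(60, 0, 2), eye = "left")
  meas <- rbind(right, left)
  s <- summarize_cohort(rbind(
    meas,
    make_eye_records(75 + rnorm(50), animal = "P2", eye = "right"),
    make_eye_records(75 + rnorm(50), animal = "P2", eye = "left")))

  pooled <- meas$thickness_um
  ctr <- mean(pooled); scl <- sqrt(mean((pooled - ctr)^2))
  z_left <- (left$thickness_um - ctr) / scl
  expect_equal(s$rz[s$animal_id == "P1" & s$eye == "left"],
               max(z_left) - min(z_left), tolerance = 1e-12)

  # per-eye scope standardizes each eye on its own
  se <- summarize_cohort(rbind(
    meas,
    make_eye_records(75 + rnorm(50), animal = "P2", eye = "right"),
    make_eye_records(75 + rnorm(50), animal = "P2", eye = "left")),
    scope = "per_eye")
  zl <- standardize(left$thickness_um)
  expect_equal(se$rz[se$animal_id == "P1" & se$eye == "left"],
               max(zl$z) - min(zl$z), tolerance = 1e-12)
})
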