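# Independent naive reimplementations of every morphometry metric (explicit
# loops, no shared code with the package) plus small fixture builders.

oracle_mean <- function(x) sum(x) / length(x)

oracle_sd_pop <- function(x) {
  m <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / length(x))
}

oracle_sd_sample <- function(x) {
  m <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}

oracle_z <- function(x, center = oracle_mean(x), scale = oracle_sd_pop(x)) {
  if (scale == 0) return(rep(0, length(x)))
  (x - center) / scale
}

oracle_ra <- function(z) {
  m <- oracle_mean(z)
  s <- 0
  for (v in z) s <- s + abs(v - m)
  s / length(z)
}

oracle_rz <- function(z) {
  mx <- z[1]; mn <- z[1]
  for (v in z) { if (v > mx) mx <- v; if (v < mn) mn <- v }
  mx - mn
}

oracle_rolling_sd <- function(x, w = 5) {
  out <- numeric(length(x) - w + 1)
  for (i in seq_along(out))
    out[i] <- oracle_sd_sample(x[i:(i + w - 1)])
  out
}

oracle_skew <- function(x) {
  m <- oracle_mean(x)
  m2 <- 0; m3 <- 0
  for (v in x) { m2 <- m2 + (v - m)^2; m3 <- m3 + (v - m)^3 }
  m2 <- m2 / length(x); m3 <- m3 / length(x)
  m3 / m2^1.5
}

oracle_exceed <- function(z, k) {
  n <- 0
  for (v in z) if (abs(v) > k) n <- n + 1
  n / length(z)
}

oracle_smooth <- function(x, w) {
  h <- (w - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(h, i - 1, n - i)
    out[i] <- oracle_mean(x[(i - k):(i + k)])
  }
  out
}

# fixture builders ----------------------------------------------------------

# measurement tibble around a constant or given thickness vector
make_eye_records <- function(thickness, animal = "P1", eye = "right",
                             slide = "A", region = "central",
                             spacing = 25) {
  tibble::tibble(
    animal_id = animal, eye = eye,
    group = if (eye == "right") "study" else "control",
    region = region, slide_id = slide,
    position_um = (seq_along(thickness) - 1) * spacing,
    thickness_um = thickness)
}

# flat band image with a tilted basal line (angle in degrees); perpendicular
# band thickness thick_px
make_tilted_band <- function(angle_deg, thick_px, W = 300, H = 200,
                             um_per_px = 1) {
  th <- angle_deg * pi / 180
  lab <- matrix(0L, H, W)
  for (cc in seq_len(W)) {
    d <- (150 - seq_len(H)) * cos(th) - (cc - 150) * sin(th)
    lab[d <= 0, cc] <- 1L
    lab[d > 0 & d <= thick_px, cc] <- 2L
  }
  labeled_image(lab, um_per_px)
}
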