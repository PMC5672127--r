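# Baseline estimation, peak detection, integration, noise and system
# suitability.

test_that("baseline recovers a flat trace and guards its window", {
  t <- seq(0, 10, by = 0.01)
  ch <- chromatogram(t, rep(5, length(t)), 205)
  bl <- estimate_baseline(ch, window = 1)
  expect_lt(max(abs(bl$baseline - 5)), 1e-9)
  expect_error(estimate_baseline(ch, window = 0.02), "5 sampling intervals")
  expect_error(estimate_baseline(ch, window = 11), "span")
})

test_that("baseline stays under a Gaussian peak for wide windows", {
  t <- seq(0, 10, by = 0.005)
  sigma <- 0.05
  y <- gaussian_trace(t, 5, sigma, area = 100 * sigma * sqrt(2 * pi))
  ch <- chromatogram(t, y, 205)
  bl <- estimate_baseline(ch, window = 8 * sigma)
  apex_idx <- which.min(abs(t - 5))
  expect_lt(bl$baseline[apex_idx], 0.05 * 100)
})

test_that("baseline tracks peak-free linear drift away from the edges", {
  t <- seq(0, 20, by = 0.01)
  drift <- 10 * t / 20
  ch <- chromatogram(t, drift, 205)
  bl <- estimate_baseline(ch, window = 0.4)
  interior <- t > 1 & t < 19
  expect_lt(max(abs(bl$baseline[interior] - drift[interior])), 0.2)
})

test_that("pure noise yields no peaks", {
  set.seed(5)
  t <- seq(0, 10, by = 0.01)
  ch <- chromatogram(t, rnorm(length(t), 0, 0.1), 205)
  bl <- estimate_baseline(ch, window = 1)
  expect_length(detect_peaks(ch, bl, min_height = 1, min_width = 0.02), 0)
})

test_that("well-resolved Gaussians are found at their true apexes", {
  t <- seq(0, 16, by = 0.005)
  apexes <- c(4.6, 6.1, 7.9, 9.4, 11.2, 13.6)
  y <- rep(2, length(t))
  for (a in apexes) y <- y + gaussian_trace(t, a, 0.06, area = 50)
  set.seed(7)
  y <- y + rnorm(length(t), 0, 0.1)
  ch <- chromatogram(t, y, 205)
  bl <- estimate_baseline(ch, window = 1)
  pk <- detect_peaks(ch, bl, min_height = 10, min_width = 0.02)
  expect_length(pk, 6)
  found <- vapply(pk, function(p) p$apex_time, numeric(1))
  expect_true(all(abs(found - apexes) <= 0.005 + 1e-12))
  expect_equal(found, sort(found))  # ordered by apex time
})

test_that("fused peaks partition the envelope at the valley", {
  t <- seq(0, 4, by = 0.001)
  sigma <- 0.05
  a1 <- 12; a2 <- 8
  y <- gaussian_trace(t, 2.0, sigma, a1) + gaussian_trace(t, 2.15, sigma, a2)
  ch <- chromatogram(t, y, 205)
  bl <- zero_baseline(ch)
  pk <- detect_peaks(ch, bl, min_height = 5, min_width = 0.005)
  expect_length(pk, 2)
  expect_equal(pk[[1]]$end_time, pk[[2]]$start_time)  # shared valley bound
  total <- sum(vapply(pk, function(p) p$area, numeric(1)))
  expect_lt(abs(total - (a1 + a2)) / (a1 + a2), 0.01)
})

test_that("trapezoidal integration matches the closed Gaussian form", {
  sigma <- 0.05
  t <- seq(0, 2, by = 0.001)
  area_true <- 100 * sigma * sqrt(2 * pi)  # amplitude 100 mAU
  ch <- chromatogram(t, gaussian_trace(t, 1, sigma, area_true), 205)
  got <- integrate_peak(ch, zero_baseline(ch), 1 - 5 * sigma, 1 + 5 * sigma)
  expect_lt(abs(got - area_true) / area_true, 0.001)
  expect_equal(area_true, 12.533, tolerance = 1e-4)
})

test_that("integration handles rectangles, zero signal and bad bounds", {
  t <- seq(0, 2, by = 0.01)
  y <- ifelse(t >= 1 & t <= 1.5, 10, 0)
  ch <- chromatogram(t, y, 205)
  expect_equal(integrate_peak(ch, zero_baseline(ch), 1, 1.5), 5.0)
  ch0 <- chromatogram(t, numeric(length(t)), 205)
  expect_equal(integrate_peak(ch0, zero_baseline(ch0), 0.2, 1.8), 0)
  expect_error(integrate_peak(ch, zero_baseline(ch), -1, 1), "outside")
  expect_error(integrate_peak(ch, zero_baseline(ch), 1.5, 1.0), "start")
})

test_that("integration is exactly additive over adjacent intervals", {
  set.seed(9)
  t <- seq(0, 5, by = 0.01)
  ch <- chromatogram(t, abs(rnorm(length(t))) + sin(t) + 1, 205)
  bl <- zero_baseline(ch)
  for (b in c(1.234, 2.5, 3.999)) {
    lhs <- integrate_peak(ch, bl, 0.5, b) + integrate_peak(ch, bl, b, 4.5)
    rhs <- integrate_peak(ch, bl, 0.5, 4.5)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("Gaussian integration error shrinks quadratically with the grid", {
  # integrate over an asymmetric window (apex - 1 sigma to apex + 5 sigma)
  # so the trapezoid error is genuinely second order; the closed form is the
  # Gaussian CDF difference
  sigma <- 0.05
  area_true <- 10
  want <- area_true * (pnorm(5) - pnorm(-1))
  errs <- vapply(c(sigma / 5, sigma / 10, sigma / 20), function(dt) {
    t <- seq(0, 2, by = dt)
    ch <- chromatogram(t, gaussian_trace(t, 1, sigma, area_true), 205)
    abs(integrate_peak(ch, zero_baseline(ch), 1 - sigma, 1 + 5 * sigma) -
          want)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 3.5 & ratios < 4.5))
})

test_that("noise estimation recovers the generator truth after detrending", {
  t <- seq(0, 20, by = 0.01)
  set.seed(21)
  flat <- chromatogram(t, rep(3, length(t)), 205)
  expect_equal(estimate_noise(flat, 1, 19)$sd, 0)

  noisy <- chromatogram(t, rnorm(length(t), 0, 1), 205)
  est <- estimate_noise(noisy, 0, 20)
  expect_lt(abs(est$sd - 1), 0.1)

  drifting <- chromatogram(t, 2 * t + rnorm(length(t), 0, 1), 205)
  est2 <- estimate_noise(drifting, 0, 20)
  expect_lt(abs(est2$sd - 1), 0.1)

  expect_error(estimate_noise(noisy, 0, 0.05), "at least 20")
  expect_error(
    estimate_noise(noisy, 1, 3, peaks = list(make_peak(2))),
    "overlaps")
})

test_that("signal-to-noise is height over noise sd", {
  nz <- structure(list(sd = 10, region_start = 0, region_end = 1,
                       n_points = 100), class = "noise_estimate")
  expect_equal(signal_to_noise(make_peak(5, height = 30), nz), 3)
  expect_equal(signal_to_noise(make_peak(5, height = 0), nz), 0)
  nz$sd <- 0
  expect_error(signal_to_noise(make_peak(5, height = 30), nz), "undefined")
})

test_that("plate count follows the half-height formula", {
  expect_equal(plate_count(make_peak(10, width_half = 0.2)), 13850)
  expect_equal(plate_count(make_peak(1, width_half = 1,
                                     start = 0.5, end = 1.5)), 5.54)
  # detected Gaussian: width_half = 2.355 sigma identity within 2%
  sigma <- 0.05
  t <- seq(8, 12, by = 0.001)
  ch <- chromatogram(t, gaussian_trace(t, 10, sigma, 10), 205)
  pk <- detect_peaks(ch, zero_baseline(ch), min_height = 1,
                     min_width = 0.01)[[1]]
  n_expect <- 5.54 * (10 / (2.355 * sigma))^2
  expect_lt(abs(plate_count(pk) - n_expect) / n_expect, 0.02)
})

test_that("resolution follows the baseline-width formula", {
  p1 <- make_peak(10, start = 9.75, end = 10.25)
  p2 <- make_peak(11, start = 10.75, end = 11.25)
  expect_equal(resolution(p1, p2), 2.0)
  expect_equal(resolution(p1, p1), 0)
  expect_error(resolution(p2, p1), "before")
  # two Gaussians 6 sigma apart with 4 sigma base widths give Rs = 1.5
  sigma <- 0.1
  g1 <- make_peak(5, start = 5 - 2 * sigma, end = 5 + 2 * sigma)
  g2 <- make_peak(5 + 6 * sigma, start = 5 + 4 * sigma, end = 5 + 8 * sigma)
  expect_equal(resolution(g1, g2), 1.5)
})

test_that("plates and resolution are invariant to uniform time rescaling", {
  p1 <- make_peak(10, start = 9.7, end = 10.3, width_half = 0.2)
  p2 <- make_peak(12, start = 11.6, end = 12.4, width_half = 0.25)
  for (c in c(0.5, 1.7, 3)) {
    s1 <- make_peak(10 * c, start = 9.7 * c, end = 10.3 * c,
                    width_half = 0.2 * c)
    s2 <- make_peak(12 * c, start = 11.6 * c, end = 12.4 * c,
                    width_half = 0.25 * c)
    expect_equal(plate_count(s1), plate_count(p1))
    expect_equal(resolution(s1, s2), resolution(p1, p2))
  }
})

test_that("detection after baseline correction ignores constant offsets", {
  t <- seq(0, 10, by = 0.005)
  y <- gaussian_trace(t, 3, 0.05, 20) + gaussian_trace(t, 6, 0.06, 30)
  set.seed(13)
  y <- y + rnorm(length(t), 0, 0.05)
  find <- function(offset) {
    ch <- chromatogram(t, y + offset, 205)
    bl <- estimate_baseline(ch, window = 1)
    detect_peaks(ch, bl, min_height = 5, min_width = 0.02)
  }
  ref <- find(0)
  shifted <- find(250)
  expect_equal(lapply(shifted, unclass), lapply(ref, unclass))
})
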