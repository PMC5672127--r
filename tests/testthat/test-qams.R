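# The single-marker model: relative correction factors, RTT peak location,
# spectral confirmation, quantitation and method comparison.

test_that("relative correction factors reproduce the validated values", {
  curves <- pub_curves()
  ref <- curves[["cholesterol"]]
  expect_equal(round(relative_correction_factor(
    curves[["7-hydroxycholesterol"]], ref), 4), 1.5354)
  expect_equal(round(relative_correction_factor(
    curves[["stigmasterol"]], ref), 4), 8.2591)
  expect_equal(round(relative_correction_factor(
    curves[["7-dehydrocholesterol"]], ref), 4), 3.0043)
  expect_equal(relative_correction_factor(ref, ref), 1.0)
})

test_that("the fitted model carries factors, wavelengths and the reference", {
  m <- qams(pub_curves(), reference = "cholesterol")
  expect_s3_class(m, "qams")
  expect_identical(coef(m)[["cholesterol"]], 1)
  expect_equal(round(coef(m)[["7-ketocholesterol"]], 4), 5.3021)
  expect_equal(round(coef(m)[["4-cholesten-3-one"]], 4), 5.4305)
  expect_equal(m$reference_slope, 206.39)
  expect_equal(unname(m$wavelengths[c("cholesterol", "7-ketocholesterol",
                                      "7-dehydrocholesterol")]),
               c(205, 240, 280))
  s <- summary(m)
  expect_true(all(s$table$intercept_ignorable))
  expect_output(print(m), "cholesterol")

  solo <- qams(pub_curves()["cholesterol"], "cholesterol")
  expect_equal(coef(solo), c(cholesterol = 1))
  expect_error(qams(pub_curves(), "ergosterol"), "no calibration curve")
})

test_that("swapping the reference gives reciprocal factors", {
  m_chol <- qams(pub_curves(), "cholesterol")
  m_stig <- qams(pub_curves(), "stigmasterol")
  expect_equal(coef(m_stig)[["cholesterol"]], 206.39 / 1704.6,
               tolerance = 1e-12)
  expect_equal(coef(m_stig)[["cholesterol"]],
               1 / coef(m_chol)[["stigmasterol"]], tolerance = 1e-9)
  # reciprocal identity over every analyte pair
  for (a in names(coef(m_chol)))
    for (b in names(coef(m_chol))) {
      f_ab <- relative_correction_factor(pub_curves()[[a]], pub_curves()[[b]])
      f_ba <- relative_correction_factor(pub_curves()[[b]], pub_curves()[[a]])
      expect_equal(f_ab * f_ba, 1, tolerance = 1e-12)
    }
})

test_that("factors are invariant to a common rescaling of all slopes", {
  curves <- pub_curves()
  for (c_scale in c(0.5, 2.8, 1000)) {
    scaled <- lapply(curves, function(cv) {
      cv$slope <- cv$slope * c_scale
      cv
    })
    m0 <- qams(curves, "cholesterol", check_intercepts = FALSE)
    m1 <- qams(scaled, "cholesterol", check_intercepts = FALSE)
    expect_equal(coef(m1), coef(m0), tolerance = 1e-12)
  }
})

test_that("a non-ignorable intercept triggers a warning in the factor", {
  good <- calibration_curve("a", 205, 500, 0.1)
  bad <- calibration_curve("b", 205, 100, 2)
  expect_warning(relative_correction_factor(bad, good), "not ignorable")
  expect_silent(relative_correction_factor(good, good))
})

test_that("single-marker quantitation inverts the slope product", {
  m <- qams(pub_curves(), "cholesterol")
  # oracle: X = Y / a_K with the analyte's own full-precision slope
  expect_equal(quantify_qams(316.9 * 10, m, "7-hydroxycholesterol"),
               10, tolerance = 1e-12)
  expect_equal(quantify_qams(0, m, "7-hydroxycholesterol"), 0)
  expect_equal(quantify_qams(206.39 * 5, m, "cholesterol"), 5)
  expect_error(quantify_qams(1, m, "ergosterol"), "not in the RCF table")
  expect_error(quantify_qams(-1, m, "cholesterol"), ">= 0")
})

test_that("ES and QAMS coincide exactly when intercepts vanish", {
  curves <- lapply(pub_curves(), function(cv) {
    cv$intercept <- 0
    cv$range_low <- NA_real_; cv$range_high <- NA_real_
    cv
  })
  m <- qams(curves, "cholesterol")
  set.seed(61)
  for (a in names(curves)) {
    areas <- runif(5, 0, 1e4)
    expect_equal(quantify_qams(areas, m, a),
                 quantify_es(areas, curves[[a]]), tolerance = 1e-12)
  }
})

test_that("ES quantitation follows the intercept-corrected inversion", {
  cv <- pub_curves()[["cholesterol"]]
  cv$range_low <- NA_real_; cv$range_high <- NA_real_
  expect_equal(quantify_es(2063.9, cv), (2063.9 + 1.93) / 206.39)
  expect_equal(round(quantify_es(2063.9, cv), 3), 10.009)
})

test_that("relative retention time is a plain invariant ratio", {
  expect_equal(relative_retention_time(12, 10), 1.2)
  expect_equal(relative_retention_time(7.5, 7.5), 1.0)
  expect_equal(relative_retention_time(12 * 1.1, 10 * 1.1),
               relative_retention_time(12, 10), tolerance = 1e-12)
  expect_error(relative_retention_time(-1, 10), "> 0")
  expect_error(relative_retention_time(5, 0), "> 0")
})

test_that("peaks are assigned to analytes by closest RTT within tolerance", {
  panel <- six_sterol_panel()
  t_ref <- 11.2
  rtts <- panel$analytes$expected_rtt
  peaks <- lapply(rtts * t_ref, function(a)
    make_peak(a, area = if (abs(a - t_ref) < 0.01) 1e5 else 50))
  asn <- assign_peaks(peaks, panel, rtt_tolerance = 0.02)
  expect_true(all(asn$assigned))
  expect_equal(asn$analyte, panel$analytes$name)
  expect_equal(asn$apex_time, rtts * t_ref, tolerance = 1e-12)
  expect_equal(asn$rtt_observed, rtts, tolerance = 1e-12)
  expect_true(all(abs(asn$rtt_deviation) < 1e-9))

  # absent analyte: drop the 7-keto peak; others unaffected
  asn2 <- assign_peaks(peaks[-2], panel, rtt_tolerance = 0.02)
  expect_false(asn2$assigned[asn2$analyte == "7-ketocholesterol"])
  expect_equal(sum(asn2$assigned), 5)

  # decoy outside the window is not assigned
  decoy <- make_peak(rtts[1] * t_ref * 1.03, area = 50)
  asn3 <- assign_peaks(c(peaks[-1], list(decoy)), panel,
                       rtt_tolerance = 0.02)
  expect_false(asn3$assigned[asn3$analyte == "7-hydroxycholesterol"])

  # no reference peak in the window
  expect_error(assign_peaks(list(make_peak(2)), panel), "reference peak")

  expect_error(assign_peaks(peaks, panel, rtt_tolerance = 0.5), "0, 0.2")
})

test_that("assignment is invariant under uniform time rescaling", {
  panel <- six_sterol_panel()
  t_ref <- 11.2
  rtts <- panel$analytes$expected_rtt
  base_areas <- c(40, 30, 20, 10, 1e5, 25)
  mk <- function(scale) lapply(seq_along(rtts), function(i)
    make_peak(rtts[i] * t_ref * scale, area = base_areas[i]))
  ref <- assign_peaks(mk(1), panel, rtt_tolerance = 0.02,
                      reference_window = NULL)
  for (scale in c(0.8, 1.1, 1.5)) {
    got <- assign_peaks(mk(scale), panel, rtt_tolerance = 0.02,
                        reference_window = NULL)
    expect_equal(got$assigned, ref$assigned)
    expect_equal(got$peak_index, ref$peak_index)
    expect_equal(got$rtt_observed, ref$rtt_observed, tolerance = 1e-12)
  }
})

test_that("spectral similarity is a scale-invariant cosine", {
  wl <- seq(200, 400, by = 5)
  sp <- data.frame(wavelength = wl, intensity = exp(-((wl - 280) / 30)^2))
  expect_equal(spectral_similarity(sp, sp), 1.0)
  neg <- sp; neg$intensity <- -neg$intensity
  expect_equal(spectral_similarity(sp, neg), -1.0)
  scaled <- sp; scaled$intensity <- 7 * scaled$intensity
  expect_equal(spectral_similarity(sp, scaled), 1.0, tolerance = 1e-12)
  flat <- sp; flat$intensity <- 5
  expect_error(spectral_similarity(sp, flat), "zero-variance")
  off <- data.frame(wavelength = wl + 1000, intensity = wl)
  expect_error(spectral_similarity(sp, off), "common wavelength")
})

test_that("mass fractions scale with extract volume over sample mass", {
  expect_equal(to_mass_fraction(74.30, sample_prep(2.0, 2.0)), 74.30)
  expect_equal(to_mass_fraction(0, sample_prep(2.0, 2.0)), 0)
  expect_equal(to_mass_fraction(10, sample_prep(1.0, 2.0)), 20)
})

test_that("method comparison reports per-analyte relative errors", {
  cmp <- compare_methods(c(a = 75.1), c(a = 75.2))
  expect_equal(cmp$relative_error[["a"]], 100 * 0.1 / 75.1,
               tolerance = 1e-9)
  expect_false(cmp$flagged)

  same <- compare_methods(c(a = 1, b = 2), c(b = 2, a = 1))
  expect_equal(unname(same$relative_error), c(0, 0))
  expect_equal(same$max_abs_re, 0)

  over <- compare_methods(c(a = 100), c(a = 103))
  expect_equal(over$relative_error[["a"]], 3)
  expect_true(over$flagged)

  expect_error(compare_methods(c(a = 0), c(a = 1)), "<= 0")
  expect_error(compare_methods(c(a = 1), c(b = 1)), "different analytes")
})
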