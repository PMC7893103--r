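test_that("predicted dose-response curves are monotone and spectrally ordered", {
  levels <- 10^seq(-1, 4, length.out = 25)
  c460 <- predict_suppression_curve(460, 10, levels, fns = fns_default)
  c600 <- predict_suppression_curve(600, 10, levels, fns = fns_default)
  expect_true(all(diff(c460$responses) >= 0))
  expect_lt(c460$responses[1], 1e-3)
  # criterion reached at lower irradiance for 460 nm than for 600 nm
  irr_at <- function(curve, center) {
    lv <- criterion_level(curve, 0.35)
    s <- scale_spd_to(narrowband_spd(center), "scotopic_lux", lv, fns_default)
    total_irradiance(s)
  }
  expect_lt(irr_at(c460, 460), irr_at(c600, 600))
})

test_that("criterion inversion recovers the half-saturation point of the logistic", {
  levels <- 10^seq(1, 4, length.out = 60)
  curve <- dose_response_curve(levels, cs_from_cla(levels))
  expect_equal(criterion_level(curve, 0.35), 355.7, tolerance = 1e-3)
  expect_identical(criterion_level(curve, curve$responses[1]), levels[1])
  expect_error(criterion_level(curve, 0.9), "saturated")
  expect_error(criterion_level(curve, -0.1), "short side")
})

test_that("criterion_level inverts the model chain at the criterion point", {
  levels <- 10^seq(0, 4, length.out = 40)
  curve <- predict_suppression_curve(470, 10, levels, fns = fns_default)
  lv <- criterion_level(curve, 0.35)
  s <- scale_spd_to(narrowband_spd(470), "scotopic_lux", lv, fns_default)
  expect_equal(cs_tf(cla_2020(s, fns_default)), 0.35, tolerance = 5e-3)
})

test_that("constant-criterion sensitivity peaks in the short-wave region and self-normalizes", {
  sens <- derive_relative_sensitivity(seq(430, 600, 10), fns = fns_default)
  expect_identical(max(sens$relative_sensitivity), 1)
  pk <- sens$wavelengths[which.max(sens$relative_sensitivity)]
  expect_gte(pk, 450)
  expect_lte(pk, 470)
  at <- function(w) sens$relative_sensitivity[match(w, sens$wavelengths)]
  expect_lt(at(600), at(500))
  # ratio-based derivation is invariant to uniform stimulus rescaling
  sens2 <- derive_relative_sensitivity(seq(430, 600, 10),
                                       reference_scotopic_lux = 30,
                                       fns = fns_default)
  expect_equal(sens2$relative_sensitivity, sens$relative_sensitivity,
               tolerance = 1e-6)
})

test_that("half-saturation fitting recovers truth and reports fit quality", {
  lv <- 500 * 10^seq(-1.2, 1.2, length.out = 8)
  clean <- data.frame(level = lv,
                      suppression = cs_from_cla(lv, cs_params(half_sat = 500)))
  ft <- fit_half_saturation(clean)
  expect_equal(ft$half_sat_estimate, 500, tolerance = 1e-3)
  expect_equal(ft$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_half_saturation(data.frame(level = c(1, 2),
                                              suppression = c(0.1, 0.2))),
               "distinct")
  expect_error(fit_half_saturation(data.frame(level = c(1, 2, 3),
                                              suppression = c(0.2, 0.2, 0.2))),
               "degenerate")
})

test_that("half-saturation recovery under noise matches the Monte-Carlo oracle", {
  # information-bound analysis: with 8 observations at sigma = 0.03 the
  # estimator SD is ~5.5% of the true value, so a 15% band should capture
  # >= 90% of replicates
  set.seed(42)
  truth <- 500
  hits <- 0
  for (i in 1:100) {
    lv <- truth * 10^seq(-0.45, 0.45, length.out = 8)
    y <- cs_from_cla(lv, cs_params(half_sat = truth)) + rnorm(8, 0, 0.03)
    ft <- fit_half_saturation(data.frame(level = lv, suppression = y))
    if (abs(ft$half_sat_estimate / truth - 1) < 0.15) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("log-abscissa alignment recovers constructed shifts", {
  levels <- 10^seq(1, 4, length.out = 50)
  a <- dose_response_curve(levels, cs_from_cla(levels))
  expect_lt(abs(align_log_shift(a, a)$shift_log10), 1e-6)
  b <- dose_response_curve(levels * 10^0.3, cs_from_cla(levels))
  expect_equal(align_log_shift(a, b)$shift_log10, -0.3, tolerance = 5e-3)
  # curves generated for t = 0.5 vs t = 1.5 differ by log10(3) on the abscissa
  ca <- dose_response_curve(levels, suppressWarnings(
    cs_tf(levels, exposure_context(0.5, 1))))
  cb <- dose_response_curve(levels, cs_tf(levels, exposure_context(1.5, 1)))
  expect_equal(abs(align_log_shift(ca, cb)$shift_log10), log10(3),
               tolerance = 0.02)
  flat_lo <- dose_response_curve(c(1, 2), c(0.0, 0.01))
  flat_hi <- dose_response_curve(c(1, 2), c(0.6, 0.65))
  expect_error(align_log_shift(flat_lo, flat_hi), "overlap")
})

test_that("duration-exponent fitting is exact on noiseless pairs and unbiased under noise", {
  exact <- data.frame(t_hours = c(0.5, 1, 2, 3),
                      half_sat = halfsat_for_duration(c(0.5, 1, 2, 3)))
  ft <- fit_duration_exponent(exact)
  expect_equal(ft$exponent, -1, tolerance = 1e-12)
  expect_equal(ft$r_squared, 1, tolerance = 1e-12)
  free <- fit_duration_exponent(exact, fix_coefficient = FALSE)
  expect_equal(free$exponent, -1, tolerance = 1e-9)
  expect_equal(free$coefficient, 355.7, tolerance = 1e-9)
  set.seed(7)
  est <- replicate(100, {
    t <- c(0.5, 1, 1.5, 2, 2.5, 3)
    k <- 355.7 * t^-1 * exp(rnorm(6, 0, 0.05))
    fit_duration_exponent(data.frame(t_hours = t, half_sat = k))$exponent
  })
  expect_lt(abs(mean(est) + 1), 0.1)
  expect_error(fit_duration_exponent(data.frame(t_hours = c(1, 2),
                                                half_sat = c(355, 177))),
               ">= 3")
  expect_error(fit_duration_exponent(data.frame(t_hours = c(1, 2, 3),
                                                half_sat = c(355, -1, 100))),
               "> 0")
})
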