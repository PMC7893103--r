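test_that("opponent sign separates cool and warm stimuli in both model versions", {
  dark <- spd(default_grid, rep(0, 401))
  for (ver in c("2005", "2020")) {
    expect_identical(opponent_by(dark, fns_default, ver), 0)
    expect_gt(opponent_by(delta_spd(450), fns_default, ver), 0)
    expect_lt(opponent_by(delta_spd(610), fns_default, ver), 0)
  }
})

test_that("rod term obeys its conventions and limits", {
  dark <- spd(default_grid, rep(0, 401))
  expect_identical(rod_term(dark, fns_default, 2.3, 1), 0)
  s <- narrowband_spd(480, total = 0.5)
  base <- rod_term(s, fns_default, 2.3, 1)
  # the bracketed ratio is homogeneous of degree 0; saturation grows with level
  big <- rod_term(spd(default_grid, 40 * s$values), fns_default, 2.3, 1)
  expect_gt(big, base)
  # saturated limit: a_rod * ratio
  vpE <- 1700^-1 * illuminance(s, "scotopic", fns_default)
  huge <- spd(default_grid, s$values * (200 * 6.5 / vpE))
  ratio <- rod_term(huge, fns_default, 2.3, 1) / 2.3
  sat_limit <- rod_term(spd(default_grid, huge$values * 1.0001),
                        fns_default, 2.3, 1) / 2.3
  expect_equal(ratio, sat_limit, tolerance = 0.01)
})

test_that("the 2005 model reproduces its calibration and warm-branch linearity", {
  a <- generate_spd("illuminant_a", grid = default_grid)
  a <- scale_spd_to(a, "photopic_lux", 1000, fns_default)
  expect_equal(cla_2005(a, fns_default), 1000, tolerance = 0.02)
  r1 <- delta_spd(610, 0.3)
  r2 <- delta_spd(610, 0.6)
  expect_equal(cla_2005(r2, fns_default), 2 * cla_2005(r1, fns_default),
               tolerance = 1e-12)
  expect_identical(cla_2005(spd(default_grid, rep(0, 401)), fns_default), 0)
})

test_that("the revised model is monotone in level and spectrally discriminating", {
  expect_identical(cla_2020(spd(default_grid, rep(0, 401)), fns_default), 0)
  nb <- narrowband_spd(460)
  cl <- vapply(10^seq(-2, 1, length.out = 30), function(a)
    cla_2020(spd(default_grid, nb$values * a), fns_default), numeric(1))
  expect_true(all(diff(cl) > 0))
  # warm LED with vs without a 480-nm notch at equal photopic lux
  comps <- list(list(center_nm = 450, fwhm_nm = 20, weight = 0.25),
                list(center_nm = 600, fwhm_nm = 90, weight = 1))
  led <- generate_spd("led_composite", list(components = comps), default_grid)
  ledn <- generate_spd("led_composite",
                       list(components = comps, notch_center_nm = 480,
                            notch_fwhm_nm = 25), default_grid)
  led <- scale_spd_to(led, "photopic_lux", 500, fns_default)
  ledn <- scale_spd_to(ledn, "photopic_lux", 500, fns_default)
  expect_false(isTRUE(all.equal(cla_2020(led, fns_default),
                                cla_2020(ledn, fns_default),
                                tolerance = 1e-3)))
})

test_that("the suppression logistic matches its printed form everywhere", {
  p <- cs_params()
  expect_identical(cs_from_cla(0), 0)
  expect_equal(cs_from_cla(355.7), 0.35, tolerance = 1e-12)
  expect_lt(abs(cs_from_cla(1e6) - 0.7), 0.01)
  # brute-force check of the printed expression at random levels
  set.seed(11)
  cla <- 10^runif(1000, -2, 6)
  brute <- 0.7 * (1 - 1 / (1 + (cla / 355.7)^1.1026))
  expect_equal(cs_from_cla(cla), brute, tolerance = 1e-12)
  expect_true(all(cs_from_cla(cla) >= 0 & cs_from_cla(cla) < 0.7))
  expect_error(cs_from_cla(-1), "cla")
})

test_that("the duration law rescales the half-saturation constant as t^-1", {
  expect_equal(halfsat_for_duration(1), 355.7)
  expect_equal(halfsat_for_duration(2), 177.85)
  expect_equal(halfsat_for_duration(0.5), 711.4)
  expect_warning(halfsat_for_duration(4), "0.5-3")
  expect_error(halfsat_for_duration(0), "> 0")
})

test_that("CS_t,f depends only on the t*f*CLA product, bit-exactly", {
  set.seed(21)
  for (i in 1:1000) {
    vals <- 10^runif(3, -1, 3)
    perms <- list(vals, vals[c(2, 3, 1)], vals[c(3, 1, 2)], vals[c(2, 1, 3)])
    outs <- vapply(perms, function(v)
      suppressWarnings(cs_tf(v[3], exposure_context(v[1], v[2]))), numeric(1))
    expect_identical(outs, rep(outs[1], 4))
  }
  expect_identical(cs_tf(355.7), cs_from_cla(355.7))
  expect_equal(cs_tf(355.7), 0.35, tolerance = 1e-12)
  expect_equal(cs_tf(177.85, exposure_context(2, 1)), 0.35, tolerance = 1e-12)
  expect_identical(suppressWarnings(cs_tf(355.7, exposure_context(1, 0.5))),
                   cs_tf(177.85, exposure_context(1, 1)))
})

test_that("the target-CS inversion is the exact inverse of CS_t,f", {
  expect_equal(cla_for_target_cs(0.35), 355.7, tolerance = 1e-9)
  expect_identical(cla_for_target_cs(0), 0)
  ctx <- exposure_context(1.5, 2)
  cla <- cla_for_target_cs(0.6, ctx)
  expect_equal(cs_tf(cla, ctx), 0.6, tolerance = 1e-9)
  expect_error(cla_for_target_cs(0.7), "unreachable")
})

test_that("exposure context warns outside its supported ranges", {
  expect_silent(exposure_context(1, 2))
  expect_warning(exposure_context(0.25, 1), "0.5-3")
  expect_warning(exposure_context(1, 1.3), "standard levels")
  expect_error(exposure_context(-1, 1), "> 0")
})

test_that("homogeneity: warm branch degree 1, rod ratio degree 0", {
  set.seed(31)
  warm <- delta_spd(620, 0.4)
  for (i in 1:20) {
    a <- 10^runif(1, -2, 2)
    scaled <- spd(default_grid, warm$values * a)
    expect_equal(cla_2005(scaled, fns_default), a * cla_2005(warm, fns_default),
                 tolerance = 1e-12)
    s <- random_led_spd()
    s2 <- spd(default_grid, s$values * 10^runif(1, -2, 2))
    r1 <- cslight:::rod_ratio(s, fns_default, 1)
    r2 <- cslight:::rod_ratio(s2, fns_default, 1)
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("report rows are internally consistent", {
  dark <- spd(default_grid, rep(0, 401))
  rep0 <- photometric_report(dark, fns_default)
  expect_identical(rep0$branch, "warm")
  expect_true(all(unlist(rep0[c("photopic_lux", "scotopic_lux", "cla_2005",
                                "cla_2020", "cs", "cs_tf")]) == 0))
  a <- generate_spd("illuminant_a", grid = default_grid)
  a <- scale_spd_to(a, "photopic_lux", 1000, fns_default)
  ra <- photometric_report(a, fns_default)
  expect_equal(ra$cla_2005, 1000, tolerance = 0.02)
  expect_identical(ra$cs, cs_from_cla(ra$cla_2020))
  blue <- scale_spd_to(narrowband_spd(460), "scotopic_lux", 300, fns_default)
  expect_identical(photometric_report(blue, fns_default)$branch, "cool")
  set.seed(41)
  for (i in 1:100) {
    s <- random_led_spd()
    r <- photometric_report(s, fns_default)
    expect_identical(r$branch,
                     if (opponent_by(s, fns_default, "2020") > 0) "cool"
                     else "warm")
  }
})
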