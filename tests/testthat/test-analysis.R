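make_profile <- function(values, w = 2, origin = 0) {
  ct_profile(window_grid(origin, w, length(values)), values)
}

test_that("support extent counts windows above the threshold fraction", {
  st <- stationary_profile(target_spec(20, 100, 10), window_grid(0, 2, 20),
                           scan_protocol(10, 10))
  expect_equal(support_extent(st, 0.05), 20)
  expect_equal(support_extent(make_profile(rep(0, 10)), 0.05), 0)
  fig3b <- make_profile(c(0, rep(20, 5), rep(0, 4)))
  expect_equal(support_extent(fig3b, 0.05), 10)  # 5w
  expect_error(support_extent(fig3b, 0), class = "cbct_config_error")
})

test_that("elongation compares supports on a shared grid", {
  g <- window_grid(0, 2, 20)
  p <- scan_protocol(10, 10)
  st <- stationary_profile(target_spec(20, 100, 10), g, p)
  expect_equal(elongation(st, st), 0)
  other <- stationary_profile(target_spec(20, 100, 10), window_grid(0, 1, 20), p)
  expect_error(elongation(other, st), class = "cbct_comparison_error")
  # A = 10 mm sinusoid, integer cycles: occupied span grows by 2A
  tg <- preset_phantom("medium", center_y0_mm = 50)
  gf <- auto_grid(tg, 10, window_width_mm = 0.5)
  stf <- stationary_profile(tg, gf, p)
  occ <- occupancy_profile_continuous(
    tg, motion_sinusoidal(10, frequency_hz = 0.25), 60, gf, 2e4)
  expect_equal(elongation(occ, stf, 1e-9), 20)
})

test_that("elongation is monotone in amplitude for the continuous oracle", {
  tg <- preset_phantom("medium", center_y0_mm = 50)
  p <- scan_protocol(10, 60)
  el <- vapply(seq(2.5, 20, by = 2.5), function(A) {
    g <- auto_grid(tg, A, window_width_mm = 0.5)
    st <- stationary_profile(tg, g, p)
    occ <- occupancy_profile_continuous(
      tg, motion_sinusoidal(A, frequency_hz = 0.25), 60, g, 1e4)
    elongation(occ, st, 1e-9)
  }, numeric(1))
  expect_true(all(diff(el) >= 0))
})

test_that("amplitude estimation inverts the elongation law", {
  expect_equal(estimate_amplitude(make_profile(rep(10, 30)), 20), 20)
  st <- stationary_profile(target_spec(20, 100, 10), window_grid(0, 2, 20),
                           scan_protocol(10, 10))
  expect_equal(estimate_amplitude(st, 20), 0)
  narrow <- make_profile(c(0, 0, 100, 0, 0, 0, 0, 0, 0, 0))
  expect_warning(a <- estimate_amplitude(narrow, 20), "smaller")
  expect_equal(a, 0)
  expect_error(estimate_amplitude(st, -3), class = "cbct_domain_error")
})

test_that("forward simulation then inversion recovers the amplitude within one window", {
  p <- scan_protocol(1000, 60)
  for (nm in c("small", "medium", "large")) {
    tg <- preset_phantom(nm, center_y0_mm = 50)
    for (A in c(5, 15)) {
      g <- auto_grid(tg, A)
      mb <- simulate_mobile_profile(
        tg, motion_sinusoidal(A, frequency_hz = 0.25), p, g)$profile
      expect_lt(abs(estimate_amplitude(mb, tg$length_y_mm, 0.02) - A), 2)
    }
  }
})

test_that("level drop is the percentage fall of the profile maximum", {
  st <- make_profile(c(0, rep(100, 10), rep(0, 9)))
  expect_equal(level_drop(st, st), 0)
  fig3b <- make_profile(c(0, rep(20, 5), rep(0, 14)))
  expect_equal(level_drop(fig3b, st), 80)
  expect_error(level_drop(st, make_profile(rep(0, 20))),
               class = "cbct_domain_error")
  # L = 20, A = 20, integer cycles: max occupancy is 1/2 (arcsine closed form)
  tg <- target_spec(20, 700, 50)
  g <- window_grid(20, 0.2, 300)
  st2 <- stationary_profile(tg, g, scan_protocol(10, 10))
  occ <- occupancy_profile_continuous(
    tg, motion_sinusoidal(20, frequency_hz = 0.25), 60, g, 2e5)
  expect_equal(level_drop(occ, st2), 50, tolerance = 1e-2)
})

test_that("split detection flags bimodal profiles and reports the dip", {
  flat <- make_profile(c(0, rep(100, 10), rep(0, 9)))
  expect_false(detect_split(flat)$split)
  bimodal <- make_profile(c(0, 10, 60, 20, 20, 55, 10, 0))
  s <- detect_split(bimodal)
  expect_true(s$split)
  expect_equal(s$dip_position_mm, 7)    # center of window 3 (value 20)
  # 3-window smoothing suppresses a single-window negative streak spike that
  # would otherwise read as a split
  spiky <- make_profile(c(0, rep(100, 3), 20, rep(100, 3), 0))
  expect_true(detect_split(spiky, dip_frac = 0.5)$split)
  expect_false(detect_split(spiky, dip_frac = 0.5, smooth_windows = 3)$split)
})

test_that("continuous-oracle profiles split exactly when the ROM exceeds the target length", {
  for (nm in c("small", "medium")) {
    tg <- preset_phantom(nm, center_y0_mm = 50)
    for (A in seq(2.5, 20, by = 2.5)) {
      g <- auto_grid(tg, A + 1)
      occ <- occupancy_profile_continuous(
        tg, motion_sinusoidal(A, frequency_hz = 0.25), 60, g, 4e4)
      expect_identical(detect_split(occ)$split, 2 * A > tg$length_y_mm)
    }
  }
})

test_that("conservation check compares profile areas at a relative tolerance", {
  st <- make_profile(c(0, rep(100, 10), rep(0, 9)))
  expect_equal(profile_integral(st), 2000)
  mb <- make_profile(c(rep(50, 20)) * 2000 / (50 * 2 * 20))
  expect_true(conservation_check(st, mb, rel_tol = 1e-9))
  off <- make_profile(rep(49, 20))
  expect_false(conservation_check(st, off, rel_tol = 1e-6))
})

test_that("prms measures normalized RMS difference over the union support", {
  g <- window_grid(0, 2, 20)
  p <- scan_protocol(10, 10)
  st <- stationary_profile(target_spec(20, 100, 10), g, p)
  expect_equal(prms(st, st)$prms_pct, 0)
  shifted <- ct_profile(g, st$values_hu + 5)
  expect_equal(prms(st, shifted, normalization_hu = 100)$prms_pct, 5)
  # symmetry and scale covariance
  other <- ct_profile(g, st$values_hu * c(rep(0.8, 10), rep(1, 10)))
  expect_equal(prms(st, other, 100)$prms_pct, prms(other, st, 100)$prms_pct)
  st3 <- ct_profile(g, st$values_hu * 3)
  other3 <- ct_profile(g, other$values_hu * 3)
  expect_equal(prms(st3, other3, 300)$prms_pct, prms(st, other, 100)$prms_pct)
  expect_error(prms(ct_profile(g, rep(0, 20)), ct_profile(g, rep(0, 20))),
               class = "cbct_domain_error")
})

test_that("prms of seeded Gaussian noise concentrates at the noise level", {
  g <- window_grid(0, 2, 40)
  model <- stationary_profile(target_spec(60, 100, 40), g,
                              scan_protocol(10, 10))
  vals <- vapply(1:50, function(s) {
    noisy <- generate_measured_profile(model, noise_spec(gaussian_sd_hu = 3,
                                                         seed = s))
    prms(model, noisy, normalization_hu = 100)$prms_pct
  }, numeric(1))
  expect_lt(abs(mean(vals) - 3), 0.5)  # 3% +- 0.5%
})

test_that("profile_metrics aggregates the per-profile measurements", {
  g <- window_grid(0, 2, 20)
  p <- scan_protocol(100, 60)
  tg <- target_spec(20, 100, 20)
  st <- stationary_profile(tg, g, p)
  mb <- simulate_mobile_profile(tg, motion_sinusoidal(5, frequency_hz = 0.25),
                                p, g)$profile
  m <- profile_metrics(mb, stationary = st, marker_length_mm = 20)
  expect_equal(m$integral_hu_mm, 2000, tolerance = 1e-9)
  expect_gte(m$elongation_mm, 0)
  expect_gte(m$level_drop_pct, -1e-9)
  expect_false(m$split)
  expect_lt(abs(m$estimated_amplitude_mm - 5), 2)
})
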