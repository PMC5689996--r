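test_that("projection times are uniform, start at zero, omit the endpoint", {
  expect_equal(projection_times(scan_protocol(10, 10)), 0:9)
  expect_equal(projection_times(scan_protocol(1, 5)), 0)
  expect_equal(projection_times(scan_protocol(4, 2)), c(0, 0.5, 1.0, 1.5))
})

test_that("stationary profile has flat top and proportional edge windows", {
  g <- window_grid(0, 2, 20)
  p <- scan_protocol(10, 10)
  aligned <- stationary_profile(target_spec(20, 100, 10), g, p)
  expect_equal(aligned$values_hu, c(rep(100, 10), rep(0, 10)))
  expect_equal(profile_integral(aligned), 2000)
  shifted <- stationary_profile(target_spec(20, 100, 11), g, p)
  expect_equal(shifted$values_hu,
               c(50, rep(100, 9), 50, rep(0, 9)))
  expect_equal(profile_integral(shifted), 2000)
  expect_error(
    stationary_profile(list(target_spec(10, 100, 10), target_spec(10, 50, 14)),
                       g, p),
    class = "cbct_config_error")
})

test_that("single voxel at constant half-window speed spreads over 5 windows with M=2", {
  g <- window_grid(0, 2, 10)
  sim <- simulate_mobile_profile(target_spec(2, 100, 2), motion_constant(1),
                                 scan_protocol(10, 10), g,
                                 deposition = "center")
  expect_equal(sim$ledger$projection_counts,
               c(0L, 2L, 2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L))
  expect_equal(sim$profile$values_hu,
               c(0, 20, 20, 20, 20, 20, 0, 0, 0, 0))
  expect_equal(mobile_level_ratio(2, 10), 0.2)
  expect_equal(support_extent(sim$profile, 0.05), 10)  # 5w
})

test_that("ten-voxel target at one window per interval spans 19 windows, peaking at the tenth", {
  g <- window_grid(0, 2, 45)
  sim <- simulate_mobile_profile(target_spec(20, 100, 12), motion_constant(2),
                                 scan_protocol(10, 10), g,
                                 deposition = "center")
  v <- sim$profile$values_hu
  first <- window_index(2 + 1e-9, g)        # target initially starts in window 1
  nz <- which(v != 0) - 1L
  expect_equal(length(nz), 19L)
  expect_equal(range(nz), c(first, first + 18L))
  expect_equal(which.max(v) - 1L - first + 1L, 10L)   # max at 10th window
  expect_equal(v[first + 19L + 1L], 0)                # 20th window empty
  expect_equal(max(sim$ledger$projection_counts), 10L)
  # triangular projection counts
  expect_equal(sim$ledger$projection_counts[(first + 1):(first + 19)],
               c(1:10, 9:1))
})

test_that("zero motion reproduces the stationary profile exactly in both modes", {
  g <- window_grid(0, 2, 30)
  p <- scan_protocol(37, 13)
  tg <- target_spec(17.2, 640, 25.3)
  for (mode in c("overlap", "center")) {
    st <- stationary_profile(tg, g, p, deposition = mode)
    mb <- simulate_mobile_profile(tg, motion_none(), p, g, deposition = mode)
    expect_identical(mb$profile$values_hu, st$values_hu)
  }
})

test_that("area is conserved and the stationary maximum is never exceeded", {
  p <- scan_protocol(500, 60)
  for (nm in c("small", "medium", "large")) {
    tg <- preset_phantom(nm, center_y0_mm = 50)
    for (A in c(2.5, 10, 20)) {
      g <- auto_grid(tg, A)
      st <- stationary_profile(tg, g, p)
      for (mode in c("overlap", "center")) {
        mb <- simulate_mobile_profile(
          tg, motion_sinusoidal(A, frequency_hz = 0.25), p, g,
          deposition = mode)$profile
        tol <- if (mode == "center") 1e-9 else 1e-6
        expect_true(conservation_check(st, mb, rel_tol = tol))
        expect_lte(max(mb$values_hu), max(st$values_hu) + 1e-9)
      }
    }
    for (vp in c(0.25, 1)) {
      g <- auto_grid(tg, vp * 60)
      st <- stationary_profile(tg, g, p)
      mb <- simulate_mobile_profile(tg, motion_constant(vp), p, g)$profile
      expect_true(conservation_check(st, mb, rel_tol = 1e-6))
    }
  }
})

test_that("a voxel leaving the imaging view raises an out-of-view error", {
  g <- window_grid(0, 2, 10)
  expect_error(
    simulate_mobile_profile(target_spec(2, 100, 15), motion_constant(2),
                            scan_protocol(10, 10), g),
    class = "cbct_fov_error")
  expect_error(
    occupancy_profile_continuous(target_spec(10, 100, 15),
                                 motion_sinusoidal(20, frequency_hz = 0.25),
                                 60, g),
    class = "cbct_fov_error")
})

test_that("constant-speed closed form obeys its limits and the conservation identity", {
  expect_equal(constant_speed_level(321, 2, 0, 10), 321)
  expect_equal(constant_speed_level(100, 2, 0.8, 10), 20)
  for (vp in c(0, 0.3, 1.7)) {
    for (tt in c(5, 60)) {
      lev <- constant_speed_level(100, 2, vp, tt)
      expect_equal(lev * (2 + vp * tt), 100 * 2)
    }
  }
  expect_error(constant_speed_level(100, 0, 1, 10), class = "cbct_domain_error")
  expect_error(constant_speed_level(100, 2, 1, 0), class = "cbct_domain_error")
  expect_error(mobile_level_ratio(11, 10), class = "cbct_domain_error")
})

test_that("discrete mean level over the broadened support matches the closed form", {
  # single voxel starting mid-window; travel VP*T a multiple of w
  w <- 2
  for (L in c(0, 2, 8, 20)) {
    vp <- L / 10
    sim <- simulate_mobile_profile(
      target_spec(w, 100, 5), motion_constant(vp), scan_protocol(1000, 10),
      window_grid(0, w, 30), deposition = "center")
    mean_level <- profile_integral(sim$profile) /
      support_extent(sim$profile, 1e-9)
    expect_equal(mean_level, constant_speed_level(100, w, vp, 10),
                 tolerance = 100 / 1000 / 100)  # CT_S / N, relative
  }
})

test_that("occupancy oracle matches the arcsine closed form for sinusoids", {
  tg <- target_spec(20, 700, 50)
  g <- window_grid(19, 2, 31)   # a window centered on the target center
  occ <- occupancy_profile_continuous(
    tg, motion_sinusoidal(20, frequency_hz = 0.25), 60, g,
    n_quadrature = 1e5)
  expected <- arcsine_occupancy_profile(tg, 20, g)
  expect_equal(occ$values_hu, expected, tolerance = 1e-3)
  # pointwise landmarks on a fine grid: center value CT_S/3, max CT_S/2 at
  # +- (A - L/2) about the center
  gf <- window_grid(20, 0.2, 300)
  occf <- occupancy_profile_continuous(
    tg, motion_sinusoidal(20, frequency_hz = 0.25), 60, gf,
    n_quadrature = 2e5)
  cf <- window_centers(gf)
  expect_equal(occf$values_hu[which.min(abs(cf - 50))], 700 / 3,
               tolerance = 2e-3)
  expect_equal(max(occf$values_hu), 700 / 2, tolerance = 5e-3)
  peaks <- cf[occf$values_hu > 0.995 * max(occf$values_hu)]
  expect_true(any(abs(peaks - 40) < 1)) # y = center - (A - L/2)
  expect_true(any(abs(peaks - 60) < 1)) # y = center + (A - L/2)
})

test_that("occupancy oracle agrees with a brute-force time-stepping oracle", {
  tg <- target_spec(10, 700, 30)
  g <- window_grid(0, 2, 30)
  mot <- motion_sinusoidal(8, frequency_hz = 0.25, phase_rad = 0.7)
  occ <- occupancy_profile_continuous(tg, mot, 12, g, n_quadrature = 5000)
  expect_equal(occ$values_hu, brute_occupancy_profile(tg, mot, 12, g, 5000),
               tolerance = 1e-9)
})

test_that("discrete overlap simulation converges to the continuous oracle", {
  tg <- preset_phantom("medium", center_y0_mm = 50)
  mot <- motion_sinusoidal(15, frequency_hz = 0.25)
  g <- auto_grid(tg, 15)
  occ <- occupancy_profile_continuous(tg, mot, 60, g, n_quadrature = 1e5)
  err <- vapply(c(100, 1000, 10000), function(N) {
    mb <- simulate_mobile_profile(tg, mot, scan_protocol(N, 60), g)$profile
    max(abs(mb$values_hu - occ$values_hu))
  }, numeric(1))
  expect_true(all(diff(err) < 0))         # decreasing in N
  expect_lt(err[3], 0.01 * 700)           # < 1% of CT_S at N = 1e4
})

test_that("profiles are phase invariant over integer cycle counts", {
  tg <- preset_phantom("medium", center_y0_mm = 50)
  g <- auto_grid(tg, 15)
  ref_c <- occupancy_profile_continuous(
    tg, motion_sinusoidal(15, frequency_hz = 0.25), 60, g, 2e4)
  ref_d <- simulate_mobile_profile(
    tg, motion_sinusoidal(15, frequency_hz = 0.25),
    scan_protocol(1000, 60), g)$profile
  for (phi in c(pi / 4, pi / 2)) {
    pc <- occupancy_profile_continuous(
      tg, motion_sinusoidal(15, frequency_hz = 0.25, phase_rad = phi),
      60, g, 2e4)
    pd <- simulate_mobile_profile(
      tg, motion_sinusoidal(15, frequency_hz = 0.25, phase_rad = phi),
      scan_protocol(1000, 60), g)$profile
    expect_lt(max(abs(pc$values_hu - ref_c$values_hu)), 1e-3 * 700)
    expect_lt(max(abs(pd$values_hu - ref_d$values_hu)), 0.01 * 700)
  }
})

test_that("occupancy profile is frequency invariant over integer cycle counts", {
  tg <- preset_phantom("small", center_y0_mm = 50)
  g <- auto_grid(tg, 15)
  p1 <- occupancy_profile_continuous(
    tg, motion_sinusoidal(15, frequency_hz = 0.2), 60, g, 4e4)
  p2 <- occupancy_profile_continuous(
    tg, motion_sinusoidal(15, frequency_hz = 0.4), 60, g, 4e4)
  expect_equal(p1$values_hu, p2$values_hu, tolerance = 1e-4)
})

test_that("constant-speed support extends by speed times duration", {
  p <- scan_protocol(2000, 60)
  g <- window_grid(0, 2, 80)
  for (vp in c(0.25, 0.5, 1.0)) {
    tg <- preset_phantom("medium", center_y0_mm = 30)
    st <- stationary_profile(tg, g, p)
    mb <- simulate_mobile_profile(tg, motion_constant(vp), p, g)$profile
    expect_lt(abs(support_extent(mb, 1e-9) - support_extent(st, 1e-9) -
                    vp * 60), 2 + 1e-9)  # +- one window
  }
})
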