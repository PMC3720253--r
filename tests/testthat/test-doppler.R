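test_that("cross-sectional areas follow the vessel geometry", {
  expect_equal(arterial_csa(0.6), pi * 0.09, tolerance = 1e-12)
  expect_equal(arterial_csa(0.6), 0.2827, tolerance = 1e-3)
  expect_equal(arterial_csa(2 / sqrt(pi)), 1, tolerance = 1e-12)
  expect_error(arterial_csa(0), "diameter")

  expect_equal(venous_csa(0.20, 0.32), 0.26)
  expect_equal(venous_csa(0.26, 0.26), 0.26)
  expect_error(venous_csa(0.3, 0.2), "csa_min")
  set.seed(4)
  for (i in 1:50) {
    lo <- runif(1, 0, 1); hi <- lo + runif(1, 0, 1)
    m <- venous_csa(lo, hi)
    expect_gte(m, lo); expect_lte(m, hi)
  }
})

test_that("Womersley number matches its closed form and is linear in radius", {
  expect_equal(womersley_number(0.3, 2 * pi * 70 / 60, 0.035),
               0.3 * sqrt(2 * pi * 70 / 60 / 0.035), tolerance = 1e-12)
  expect_equal(womersley_number(0.3, 2 * pi * 70 / 60, 0.035), 4.34,
               tolerance = 5e-3)
  expect_equal(womersley_number(0.3, 0, 0.035), 0)
  expect_equal(womersley_number(0.6, 3, 0.035),
               2 * womersley_number(0.3, 3, 0.035))
  expect_error(womersley_number(-1, 3, 0.035), "radius")
})

test_that("velocity factor spans Poiseuille to plug flow monotonically", {
  expect_equal(velocity_factor(0), 2)
  expect_lt(abs(velocity_factor(100) - 1), 0.05)
  grid <- velocity_factor(seq(0, 20, by = 0.25))
  expect_true(all(diff(grid) <= 1e-10))
  expect_true(all(grid > 1 - 1e-12 & grid <= 2))
  expect_error(velocity_factor(-0.1), "alpha")
})

test_that("peak-to-mean velocity conversion round-trips", {
  expect_equal(tav_from_peak(40, 2), 20)
  expect_equal(tav_from_peak(40, 1), 40)
  set.seed(8)
  x <- runif(20, 0, 100); eta <- runif(20, 1, 2)
  expect_equal(tav_from_peak(x, eta) * eta, x, tolerance = 1e-12)
  expect_error(tav_from_peak(10, 0.9), "eta")
})

test_that("five-point profile mean uses no-slip trapezoid over the chord", {
  # constant profile: 7 nodes (0, v x5, 0), h = 1/6 -> 5v/6
  expect_equal(tav_from_profile(rep(12, 5)), 10, tolerance = 1e-12)
  expect_equal(tav_from_profile(rep(0, 5)), 0)
  # parabola sampled at the 5 interior nodes: analytic chord mean is 2V/3
  V <- 30
  xs <- (1:5) / 6
  samples <- V * 4 * xs * (1 - xs)
  got <- tav_from_profile(samples)
  expect_equal(got, 35 * V / 54, tolerance = 1e-12)
  expect_lt(abs(got - 2 * V / 3) / (2 * V / 3), 0.05)
  # reversed flow stays signed
  expect_lt(tav_from_profile(rep(-10, 5)), 0)
  expect_error(tav_from_profile(1:4), "5")
})

test_that("angle uncertainty is zero iff epsilon is zero and grows with angle", {
  expect_equal(tav_uncertainty(1, 60, 5), 0.1831, tolerance = 1e-4)
  expect_equal(tav_uncertainty(50, 45, 0), 0)
  thetas <- seq(20, 75, by = 5)
  d <- tav_uncertainty(1, thetas, 5)
  expect_true(all(d > 0))
  expect_true(all(diff(d) > 0))          # increasing in theta
  eps <- seq(0.5, 10, by = 0.5)
  d2 <- tav_uncertainty(1, 50, eps)
  expect_true(all(diff(d2) > 0))         # increasing in epsilon
  expect_error(tav_uncertainty(1, 88, 5), "90")
})

test_that("flow and its uncertainty scale linearly and share relative error", {
  expect_equal(flow_uncertainty(0, 5), 0)
  expect_equal(flow_uncertainty(2, 0.5), 60)
  m <- vessel_measurement("s", "HC", "supine", "IJV", "right", "J3",
                          tavp = 10, csa_min = 0.5, csa_max = 0.5,
                          doppler_angle = 55)
  cfg <- flow_config(eta_override = list(vein = 1))
  f <- compute_flow(m, cfg)
  expect_equal(f$q, 10 * 0.5 * 60)
  # dQ/Q == dTAV/TAV at any site
  expect_equal(f$dq / f$q, tav_uncertainty(1, 55, 5), tolerance = 1e-12)
  # q linear in tav and csa
  m2 <- m; m2$tavp <- 30
  expect_equal(compute_flow(m2, cfg)$q, 3 * f$q, tolerance = 1e-12)
  m3 <- m; m3$csa_min <- 1.0; m3$csa_max <- 1.0
  expect_equal(compute_flow(m3, cfg)$q, 2 * f$q, tolerance = 1e-12)
})

test_that("absent flow quantifies to zero and profile records dispatch", {
  m <- vessel_measurement("s", "CCSVI", "supine", "IJV", "right", "J1",
                          tavp = 0, csa_min = 0.3, csa_max = 0.5,
                          doppler_angle = 55, flow_state = "absent")
  f <- compute_flow(m)
  expect_equal(f$q, 0)
  expect_equal(f$dq, 0)
  expect_equal(f$method, "absent")

  mp <- vessel_measurement("s", "CCSVI", "supine", "IJV", "left", "J1",
                           profile_velocities = c(4, 8, 10, 8, 4),
                           csa_min = 0.2, csa_max = 0.4, doppler_angle = 55,
                           flow_state = "turbulent")
  fp <- compute_flow(mp)
  expect_equal(fp$method, "profile5")
  expect_equal(fp$tav, tav_from_profile(c(4, 8, 10, 8, 4)))
  expect_equal(fp$q, fp$tav * 0.3 * 60, tolerance = 1e-12)
})

test_that("eta overrides replace the Womersley value per vessel class", {
  m <- dplyr::bind_rows(
    vessel_measurement("s", "HC", "supine", "CCA", "right",
                       tavp = 40, diameter = 0.6, doppler_angle = 50),
    vessel_measurement("s", "HC", "supine", "IJV", "right", "J2",
                       tavp = 40, csa_min = 0.3, csa_max = 0.3,
                       doppler_angle = 50))
  f <- compute_flow(m, flow_config(eta_override = list(artery = 1.5,
                                                       vein = 1.25)))
  expect_equal(f$eta, c(1.5, 1.25))
  expect_equal(f$tav, c(40 / 1.5, 40 / 1.25))
})
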