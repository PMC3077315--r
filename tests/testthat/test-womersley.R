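test_that("zero flow amplitude gives an identically zero field", {
  fl <- womersley_from_flow_amplitude(0, 0.635, 2 * pi, water())
  expect_identical(Mod(fl$gradient_amplitude), 0)
  expect_identical(womersley_velocity(fl, 0.3, 0.2), 0)
  expect_identical(womersley_flow_rate(fl, c(0, 0.25)), c(0, 0))
})

test_that("small-alpha limit recovers Poiseuille gradient and profile", {
  R <- 0.5; q0 <- 0.3
  fluid <- water()
  omega <- (0.05 / R)^2 * fluid$kinematic_viscosity  # alpha = 0.05
  fl <- womersley_from_flow_amplitude(q0, R, omega, fluid)
  expect_equal(fl$womersley_alpha, 0.05)
  k_pois <- 8 * fluid$dynamic_viscosity * q0 / (pi * R^4)
  expect_equal(Mod(fl$gradient_amplitude), k_pois, tolerance = 0.01)
  # parabolic profile: centerline / cross-section mean = 2
  t_pk <- (pi / 2) / omega  # peak of Q(t) = q0 sin
  vbar <- q0 / (pi * R^2)
  expect_equal(womersley_velocity(fl, 0, t_pk) / vbar, 2, tolerance = 0.01)
  # viscous-limit pressure force amplitude -> Poiseuille drop * S * L
  geom <- conduit_geometry(2 * R, 3)
  fp <- womersley_pressure_force_waveform(fl, geom, 64)
  expect_equal(max(abs(fp$values)),
               k_pois * geom$cross_section_area * geom$axial_length,
               tolerance = 0.01)
})

test_that("no-slip, axisymmetry and domain checks hold", {
  fl <- std_flow16()
  for (t in c(0, 0.13, 0.61))
    expect_equal(womersley_velocity(fl, fl$radius, t), 0, tolerance = 1e-12)
  expect_equal(womersley_velocity(fl, -0.3, 0.2),
               womersley_velocity(fl, 0.3, 0.2))
  expect_error(womersley_velocity(fl, fl$radius * 1.01, 0), "domain")
})

test_that("radial quadrature of the profile reproduces the flow waveform", {
  # mass consistency across regimes, including at peak flow
  for (a in c(0.5, 5, 16)) {
    fl <- phantom_flow(alpha = a)
    q0 <- ml_min_to_cm3s(46)
    for (t in c(fl$period / 4, 0.1 * fl$period, 0.8 * fl$period)) {
      q_quad <- stats::integrate(
        function(r) womersley_velocity(fl, r, t) * 2 * pi * r,
        0, fl$radius, rel.tol = 1e-10, abs.tol = 1e-13)$value
      expect_lt(abs(q_quad - womersley_flow_rate(fl, t)), 1e-6 * q0)
    }
  }
})

test_that("flow waveform is a zero-mean periodic sinusoid of amplitude q0", {
  fl <- std_flow16()
  q0 <- ml_min_to_cm3s(46)
  tt <- seq(0, fl$period, length.out = 4001)
  q <- womersley_flow_rate(fl, tt)
  expect_equal(max(abs(q)), q0, tolerance = 1e-9)
  wf <- womersley_flow_waveform(fl, 64)
  expect_lt(abs(mean(wf$values)), 1e-10 * q0)
  expect_equal(womersley_flow_rate(fl, tt + fl$period), q, tolerance = 1e-12)
  # phase convention: Q(t) = q0 sin(omega t)
  expect_equal(q, q0 * sin(fl$angular_frequency * tt), tolerance = 1e-9)
})

test_that("pressure force follows the exact Bessel relation at alpha = 16", {
  # independent route: frozen scipy J0/J1 at Lambda = 16 exp(i 3 pi/4)
  j0 <- -659.496904359 - 8190.71002021i
  j1 <- 8024.83148367 - 459.776180966i
  lam <- complex(modulus = 16, argument = 3 * pi / 4)
  f_lam <- 2 * j1 / (lam * j0)
  q0 <- ml_min_to_cm3s(46)
  fl <- phantom_flow(alpha = 16)
  geom <- phantom_geometry()
  k_exact <- q0 * fl$fluid$density * fl$angular_frequency /
    (pi * fl$radius^2 * Mod(1 - f_lam))
  fp <- womersley_pressure_force_waveform(fl, geom, 256)
  amp <- fit_sinusoid(fp, fl$angular_frequency / (2 * pi))$amplitude
  expect_equal(amp, k_exact * geom$cross_section_area * geom$axial_length,
               tolerance = 1e-8)
  # the exact amplitude exceeds the inertial limit rho L omega q0 by the
  # Stokes-layer factor 1/|1 - F| ~ 1.092 at alpha = 16
  inertial_limit <- fl$fluid$density * geom$axial_length *
    fl$angular_frequency * q0
  expect_equal(amp / inertial_limit, 1 / Mod(1 - f_lam), tolerance = 1e-8)
  expect_gt(amp / inertial_limit, 1.08)
})

test_that("high-alpha inertial limit: amplitude and 90-degree phase lead", {
  q0 <- 0.5; R <- 0.635
  fluid <- water()
  omega <- (200 / R)^2 * fluid$kinematic_viscosity  # alpha = 200
  fl <- womersley_from_flow_amplitude(q0, R, omega, fluid)
  geom <- conduit_geometry(2 * R, 3.81)
  fp <- womersley_pressure_force_waveform(fl, geom, 128)
  expect_equal(max(abs(fp$values)),
               fluid$density * geom$axial_length * omega * q0,
               tolerance = 0.02)
  # pressure leads flow by ~90 degrees: F_p ~ +cos at Q ~ +sin
  fit_p <- fit_sinusoid(fp, omega / (2 * pi))
  expect_equal(fit_p$phase, pi / 2, tolerance = 0.02)
  expect_error(
    womersley_pressure_force_waveform(fl, conduit_geometry(2.2 * R, 3.81), 16),
    "configuration")
})

test_that("zero gradient amplitude gives a zero pressure force", {
  fl <- womersley_from_flow_amplitude(0, 0.635, 2 * pi, water())
  fp <- womersley_pressure_force_waveform(fl, phantom_geometry(), 16)
  expect_identical(fp$values, rep(0, 16))
})
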