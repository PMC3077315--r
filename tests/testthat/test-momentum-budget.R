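# small hand-built series: uniform velocity v0 over an n-pixel block ROI
block_series <- function(v0 = 1, n_pix = 32, h = 0.2, n_phases = 3) {
  m <- 16
  acq <- acquisition_geometry(m * h, m, 1, n_phases, 1, 20)
  mask <- matrix(FALSE, m, m)
  mask[3:6, 3:10] <- TRUE  # 4 x 8 = 32 pixels
  stopifnot(sum(mask) == n_pix)
  vel <- array(0, c(m, m, n_phases))
  for (k in seq_len(n_phases)) vel[, , k][mask] <- v0
  mag <- array(0.2, c(m, m, n_phases))
  for (k in seq_len(n_phases)) mag[, , k][mask] <- 1
  list(series = velocity_series(vel, mag, acq,
                                (seq_len(n_phases) - 1) / n_phases),
       mask = roi_mask(mask, h))
}

test_that("pixel-sum flow rate: uniform field, phantom accuracy, refinement", {
  b <- block_series(v0 = 1)
  q <- flow_rate(b$series, b$mask)
  expect_equal(q$values, rep(1.28, 3))  # 32 * 0.04 cm^2 * 1 cm/s
  expect_identical(q$units, "cm3/s")
  # noise-free alpha = 16 phantom: amplitude within ~6% of 46 mL/min
  s <- std_series_centered()
  mask <- segment_series(s)
  qf <- flow_rate(s, mask)
  amp <- fit_sinusoid(qf, 1 / s$acquisition$cycle_period)$amplitude
  expect_lt(abs(cm3s_to_ml_min(amp) - 46) / 46, 0.06)
  # refined 0.02 cm grid: amplitude within 0.5% of analytic
  fl <- std_flow16()
  acq_fine <- fine_acq(fl$period, 0.02, n_phases = 17)
  s_fine <- render_series(fl, acq_fine)
  q_fine <- flow_rate(s_fine, segment_series(s_fine))
  amp_fine <- fit_sinusoid(q_fine, 1 / fl$period)$amplitude
  expect_lt(abs(amp_fine - ml_min_to_cm3s(46)) / ml_min_to_cm3s(46), 0.005)
  # empty mask errors
  expect_error(flow_rate(s, roi_mask(matrix(c(TRUE, rep(FALSE, 3)), 2), 0.2)),
               "configuration")
})

test_that("mass balance relates inflows and production to volume change", {
  q <- waveform(sin(2 * pi * (0:15) / 16), 1, "cm3/s")
  expect_equal(mass_balance_volume_rate(list(q))$values, q$values)
  # CSF-scale production alone: constant dV/dt of 0.36 mL/min
  zero <- waveform(rep(0, 16), 1, "cm3/s")
  dv <- mass_balance_volume_rate(list(zero), net_production = ml_min_to_cm3s(0.36))
  expect_equal(cm3s_to_ml_min(dv$values), rep(0.36, 16))
  # inflow + equal outflow cancel
  neg <- waveform(-q$values, 1, "cm3/s")
  expect_equal(mass_balance_volume_rate(list(q, neg))$values, rep(0, 16))
  expect_error(mass_balance_volume_rate(list(q, waveform(1:5, 1, "cm3/s"))),
               "configuration")
})

test_that("momentum inflow is rho sum v^2 S with the parabolic 4/3 factor", {
  b <- block_series(v0 = 1)
  fm <- momentum_inflow(b$series, b$mask, water())
  expect_equal(fm$values, rep(1.28, 3))
  b0 <- block_series(v0 = 0)
  expect_identical(momentum_inflow(b0$series, b0$mask, water())$values,
                   rep(0, 3))
  # fine-grid Poiseuille: momentum coefficient 4/3 over mean-velocity flux
  p <- poiseuille_series(q = 0.7667, h = 0.0125)
  fmp <- momentum_inflow(p$series, p$mask, water())
  S <- pi * 0.635^2
  vbar <- 0.7667 / S
  expect_equal(fmp$values[1], (4 / 3) * vbar^2 * S, tolerance = 0.01)
})

test_that("inertial force is rho L dQ/dt with known discrete-operator response", {
  geom <- phantom_geometry()
  const <- waveform(rep(2.5, 17), 1, "cm3/s")
  expect_equal(inertial_force(const, water(), geom)$values, rep(0, 17))
  # single harmonic, spectral: exact amplitude rho L omega Q0
  q0 <- 0.768; n <- 17
  q <- waveform(q0 * sin(2 * pi * (0:(n - 1)) / n), 1, "cm3/s")
  fi_sp <- inertial_force(q, water(), geom, "spectral")
  amp_sp <- fit_sinusoid(fi_sp, 1)$amplitude
  expect_equal(amp_sp, 1 * 3.81 * 2 * pi * q0, tolerance = 1e-6)
  expect_equal(1 * 3.81 * 2 * pi * q0, 18.4, tolerance = 2e-3)
  # central difference attenuates by sin(w dt)/(w dt)
  fi_ce <- inertial_force(q, water(), geom, "central")
  amp_ce <- fit_sinusoid(fi_ce, 1)$amplitude
  wdt <- 2 * pi / n
  expect_equal(amp_ce / amp_sp, sin(wdt) / wdt, tolerance = 1e-9)
  expect_error(inertial_force(waveform(1:2, 1, "cm3/s"), water(), geom),
               "insufficient")
})

test_that("viscous drag estimator matches Poiseuille wall shear on a fine grid", {
  geom <- phantom_geometry()
  # zero field -> zero force
  b0 <- block_series(v0 = 0)
  expect_identical(viscous_force(b0$series, b0$mask, water(), geom)$values,
                   rep(0, 3))
  # steady Poiseuille, 0.0125 cm grid: -8 mu L Q / R^2 within 10%
  qs <- 0.7667
  p <- poiseuille_series(q = qs, h = 0.0125)
  fv <- viscous_force(p$series, p$mask, water(), geom)
  drag <- -8 * 0.01 * 3.81 * qs / 0.635^2
  expect_equal(fv$values[1], drag, tolerance = 0.10)
  # drag opposes the flow: all-positive velocities give F_V <= 0
  expect_true(all(fv$values <= 0))
  p_neg <- poiseuille_series(q = qs, h = 0.05)
  p_neg$series$velocity <- -p_neg$series$velocity
  expect_true(all(viscous_force(p_neg$series, p_neg$mask, water(),
                                geom)$values >= 0))
})

test_that("body force is rho V (g - a), zero for the horizontal phantom", {
  expect_identical(body_force(water(), 4.8), 0)
  expect_equal(body_force(fluid_properties(1, 0.01), 1, axial_gravity = 981),
               981)
  expect_equal(body_force(water(), 2, 981, 100), 2 * (981 - 100))
  expect_equal(body_force(water(), 2, 500, 0) + body_force(water(), 2, 0, -481),
               body_force(water(), 2, 981, 0))
})

test_that("pressure force solves the momentum balance in both modes", {
  fi <- waveform(18 * cos(2 * pi * (0:16) / 17), 1, "dyne")
  expect_identical(pressure_force_cv(fi, "simplified")$values, fi$values)
  z <- waveform(rep(0, 17), 1, "dyne")
  full0 <- pressure_force_cv(fi, "full", momentum_in = z, momentum_out = z,
                             viscous = z, body = 0)
  expect_identical(full0$values, fi$values)
  expect_error(pressure_force_cv(fi, "full"), "configuration")
  # full mode adds the drag the pressure must overcome (-F_V, F_V <= 0)
  fv <- waveform(rep(-0.5, 17), 1, "dyne")
  full <- pressure_force_cv(fi, "full", momentum_in = z, momentum_out = z,
                            viscous = fv, body = 0)
  expect_equal(full$values, fi$values + 0.5)
})

test_that("Urchuk-Plewes estimator recovers gradients on reference fields", {
  geom <- phantom_geometry()
  b0 <- block_series(v0 = 0, h = 0.2)
  # a 4x8 block has interior pixels; zero field gives zero everywhere
  up0 <- urchuk_plewes(b0$series, b0$mask, water(), geom)
  expect_identical(up0$gradient$values, rep(0, 3))
  expect_identical(up0$force$values, rep(0, 3))
  # steady fine-grid Poiseuille: -dp/dz -> 8 mu Q / (pi R^4) within 5%
  qs <- 0.7667
  p <- poiseuille_series(q = qs, h = 0.0125)
  up <- urchuk_plewes(p$series, p$mask, water(), geom)
  g_pois <- 8 * 0.01 * qs / (pi * 0.635^4)  # dyne/cm^3
  expect_equal(up$gradient$values[1], dyne_cm3_to_pa_cm(g_pois),
               tolerance = 0.05)
  expect_equal(up$viscous_part$values[1], up$gradient$values[1],
               tolerance = 1e-9)  # steady: all viscous
  # refined oscillatory flow: UP inertial part vs CV inertial force, 5% rms
  fl <- std_flow16()
  acq <- fine_acq(fl$period, 0.025, n_phases = 64)
  s <- render_series(fl, acq)
  mask <- segment_series(s)
  upf <- urchuk_plewes(s, mask, water(), geom)
  fi <- inertial_force(flow_rate(s, mask), water(), geom, "central")
  rms <- sqrt(mean((upf$force_inertial$values - fi$values)^2))
  expect_lt(rms / max(abs(fi$values)), 0.05)
  # degenerate ROI: a single row has no full stencil
  row <- matrix(FALSE, 16, 16); row[8, 3:10] <- TRUE
  b <- block_series(v0 = 1)
  expect_error(urchuk_plewes(b$series, roi_mask(row, 0.2), water(), geom),
               "degenerate-ROI")
})

test_that("noise propagation gives sigma_q = sigma_v S_pix sqrt(N) and scales", {
  fl <- std_flow16()
  acq <- phantom_acq(fl$period)
  mask32 <- segment_series(render_series(fl, acq, grid_placement(c(0.5, 0.5))))
  rep <- propagate_uncertainty(acq, 25, mask32, water(), phantom_geometry())
  expect_equal(rep$sigma_q, velocity_noise_sigma(20, 25) * 0.04 * sqrt(32))
  expect_equal(rep$sigma_q, 0.0815, tolerance = 1e-2)
  expect_equal(cm3s_to_ml_min(rep$sigma_q), 4.9, tolerance = 1e-2)
  # snr -> infinity gives vanishing uncertainties
  rep_hi <- propagate_uncertainty(acq, 1e12, mask32, water(), phantom_geometry())
  expect_lt(rep_hi$sigma_q, 1e-10)
  expect_lt(rep_hi$sigma_inertial, 1e-8)
  # sqrt(N) scaling over random block masks
  set.seed(5)
  for (n_col in c(2, 5, 8)) {
    mk <- matrix(FALSE, 16, 16); mk[3:6, seq_len(n_col) + 2] <- TRUE
    r <- propagate_uncertainty(acq, 25, roi_mask(mk, 0.2), water(),
                               phantom_geometry())
    expect_equal(r$sigma_q,
                 velocity_noise_sigma(20, 25) * 0.04 * sqrt(4 * n_col))
  }
  # central-difference derivative gain is 1/(sqrt(2) dt)
  dt <- acq$cycle_period / acq$n_phases
  expect_equal(rep$sigma_inertial,
               1 * 3.81 * rep$sigma_q / (sqrt(2) * dt))
})

test_that("empirical flow noise matches the propagated sigma_q", {
  fl <- std_flow16()
  acq <- fine_acq(fl$period, 0.2, n_phases = 5)  # small grid, many seeds
  s_clean <- render_series(fl, acq)
  mask <- segment_series(s_clean)
  q_clean <- flow_rate(s_clean, mask)
  dev <- unlist(lapply(1:40, function(seed) {
    flow_rate(add_noise(s_clean, 25, seed), mask)$values - q_clean$values
  }))
  sigma_q <- propagate_uncertainty(acq, 25, mask, water(),
                                   phantom_geometry())$sigma_q
  expect_equal(sd(dev), sigma_q, tolerance = 0.10)
})

test_that("momentum_budget assembles a consistent simplified budget", {
  s <- add_noise(std_series_centered(), 25, 77)
  mask <- segment_series(s)
  bud <- momentum_budget(s, mask, water(), phantom_geometry(), snr = 25)
  expect_identical(bud$pressure_force_cv$values, bud$inertial_force$values)
  expect_identical(bud$body_force, 0)
  expect_equal(bud$pressure_gradient$values,
               force_to_gradient(bud$pressure_force_cv$values,
                                 phantom_geometry()))
  expect_s3_class(bud$uncertainty, "uncertainty_report")
  # full mode with the short-conduit assumption differs only by -F_V
  bud_full <- momentum_budget(s, mask, water(), phantom_geometry(),
                              mode = "full")
  expect_equal(bud_full$pressure_force_cv$values,
               bud$inertial_force$values - bud$viscous_force$values)
})
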