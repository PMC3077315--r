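test_that("pixel-center rendering reproduces the printed ROI pixel counts", {
  # independent lattice-point oracle vs the rendered magnitude support
  expect_identical(lattice_count(0.635, 0.2, c(0, 0)), 37L)
  expect_identical(lattice_count(0.635, 0.2, c(0.5, 0.5)), 32L)
  s_c <- std_series_centered()
  expect_identical(sum(s_c$magnitude[, , 1] == 1), 37L)
  fl <- std_flow16()
  s_o <- render_series(fl, phantom_acq(fl$period), grid_placement(c(0.5, 0.5)))
  expect_identical(sum(s_o$magnitude[, , 1] == 1), 32L)
})

test_that("velocity is exactly zero outside the lumen and zero flow renders zero", {
  s <- std_series_centered()
  outside <- s$magnitude[, , 1] != 1
  for (k in c(1, 9)) expect_identical(unique(s$velocity[, , k][outside]), 0)
  fl0 <- womersley_from_flow_amplitude(0, 0.635, 2 * pi, water())
  s0 <- render_series(fl0, phantom_acq(1))
  expect_identical(max(abs(s0$velocity)), 0)
  # lumen larger than grid errors out
  big <- womersley_from_flow_amplitude(0.5, 3, 2 * pi, water())
  expect_error(render_series(big, acquisition_geometry(6, 30, 1, 17, 1, 20)),
               "lumen larger")
})

test_that("supersampled edge pixels converge to the sub-pixel area average", {
  fl <- std_flow16()
  acq <- fine_acq(fl$period, 0.2, n_phases = 3)
  s16 <- render_series(fl, acq, grid_placement(supersample = 16L))
  # pick an edge pixel: partial lumen coverage
  frac <- (s16$magnitude[, , 1] - 0.2) / 0.8
  idx <- which(frac > 0.2 & frac < 0.8, arr.ind = TRUE)[1, ]
  ic <- floor(acq$matrix_size / 2) + 1
  h <- acq$pixel_spacing
  # quadrature oracle: dense 200x200 sub-grid mean over that pixel
  g <- (seq_len(200) - 0.5) / 200 - 0.5
  xs <- (idx[2] - ic + g) * h
  ys <- (idx[1] - ic + g) * h
  rr <- sqrt(outer(ys^2, xs^2, `+`))
  vv <- matrix(0, 200, 200)
  vv[rr < fl$radius] <- womersley_velocity(fl, rr[rr < fl$radius],
                                           s16$timestamps[2])
  expect_equal(s16$velocity[idx[1], idx[2], 2], mean(vv), tolerance = 5e-3)
  expect_equal(frac[idx[1], idx[2]], mean(rr < fl$radius), tolerance = 5e-3)
})

test_that("noise injection is calibrated, seeded and non-destructive", {
  s <- std_series_centered()
  n1 <- add_noise(s, 25, 123)
  n2 <- add_noise(s, 25, 123)
  expect_identical(n1$velocity, n2$velocity)
  expect_identical(n1$magnitude, n2$magnitude)
  expect_false(identical(n1$velocity, add_noise(s, 25, 124)$velocity))
  # noiseless limit
  hi <- add_noise(s, 1e9, 1)
  expect_lt(max(abs(hi$velocity - s$velocity)), 1e-6)
  # empirical sd over all pixels (128^2 x 17 >> 1e4) within 3% of sigma_v
  dv <- n1$velocity - s$velocity
  expect_equal(sd(dv), velocity_noise_sigma(20, 25), tolerance = 0.03)
  dm <- n1$magnitude - s$magnitude
  expect_equal(sd(dm), 1 / 25, tolerance = 0.03)
  # the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(add_noise(s, 25, 5)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("velocity wrapping is modular into [-venc, venc]", {
  fl <- std_flow16()
  acq <- phantom_acq(fl$period, venc = 10)
  s <- render_series(fl, acq)
  s$velocity[1, 1, 1] <- 11
  s$velocity[1, 2, 1] <- -10.5
  w <- wrap_velocity(s)
  expect_equal(w$velocity[1, 1, 1], -9)
  expect_equal(w$velocity[1, 2, 1], 9.5)
  expect_true(all(abs(w$velocity) <= 10))
  # values already in (-venc, venc] unchanged
  inr <- abs(s$velocity) < 10 & s$velocity != 0
  expect_identical(w$velocity[inr], s$velocity[inr])
})

test_that("sensor trace tiles the waveform and averages down as 1/sqrt(n)", {
  wf <- waveform(2.5 * sin(2 * pi * (0:99) / 100), 1, "Pa")
  tr <- simulate_sensor_trace(wf, 5000, 3, noise_sigma = 0)
  expect_identical(nrow(tr), 15000L)
  # noise-free round trip: one sample per bin, at the bin's left edge
  pa <- phase_average(simulate_sensor_trace(wf, 100, 3), 1, 100)
  expect_equal(pa$values, wf$values, tolerance = 1e-10)
  # phase-averaged noise shrinks as 1/sqrt(12 cycles): one sample per bin
  # per cycle at 100 Hz / 100 bins
  trn <- simulate_sensor_trace(wf, 100, 12, noise_sigma = 0.10, seed = 31)
  pan <- phase_average(trn, 1, 100)
  resid <- pan$values - wf$values
  expect_equal(sd(resid), 0.10 / sqrt(12), tolerance = 0.20)
})
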