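# Shared fixture builders for the synthetic phantom world. Everything is
# generated in code at test time; expensive renders are memoised per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Womersley solution at phantom scale; alpha fixes omega when given,
# otherwise omega = 2 pi frequency (alpha ~ 15.92 at 1 Hz)
phantom_flow <- function(alpha = NULL, frequency = 1, q0_ml_min = 46,
                         radius = 0.635, fluid = water()) {
  omega <- if (is.null(alpha)) 2 * pi * frequency
           else (alpha / radius)^2 * fluid$kinematic_viscosity
  womersley_from_flow_amplitude(ml_min_to_cm3s(q0_ml_min), radius, omega,
                                fluid)
}

phantom_acq <- function(period, n_phases = 17, venc = 20,
                        field_of_view = 25.6, matrix_size = 128,
                        slice_thickness = 1) {
  acquisition_geometry(field_of_view, matrix_size, slice_thickness,
                       n_phases, period, venc)
}

# a fine acquisition grid just covering the lumen, for refinement studies
fine_acq <- function(period, pixel_spacing, n_phases = 17, venc = 20,
                     radius = 0.635) {
  m <- 2 * ceiling(radius / pixel_spacing) + 8
  acquisition_geometry(m * pixel_spacing, m, 1, n_phases, period, venc)
}

phantom_geometry <- function() conduit_geometry(1.27, 3.81)

# noise-free alpha = 16 series on the acquisition grid, centered lumen
std_series_centered <- function() cached("std_centered", {
  fl <- phantom_flow(alpha = 16)
  render_series(fl, phantom_acq(fl$period))
})

std_flow16 <- function() cached("flow16", phantom_flow(alpha = 16))

# steady Poiseuille profile rendered by hand on a grid of spacing h;
# returns list(series, mask) with at least 3 identical phases
poiseuille_series <- function(q, h, radius = 0.635, n_phases = 3) {
  m <- 2 * ceiling(radius / h) + 8
  acq <- acquisition_geometry(m * h, m, 1, n_phases, 1, 20)
  ic <- floor(m / 2) + 1
  x <- (seq_len(m) - ic) * h
  rr <- sqrt(outer(rep(1, m), x)^2 + outer(x, rep(1, m))^2)
  inside <- rr < radius
  vmax <- 2 * q / (pi * radius^2)
  v <- matrix(0, m, m)
  v[inside] <- vmax * (1 - (rr[inside] / radius)^2)
  vel <- array(rep(v, n_phases), c(m, m, n_phases))
  mag <- array(rep(inside + 0.2 * !inside, n_phases), c(m, m, n_phases))
  series <- velocity_series(vel, mag, acq,
                            (seq_len(n_phases) - 1) / n_phases)
  list(series = series, mask = roi_mask(inside, h))
}

# independent lattice-point oracle for in-lumen pixel counts
lattice_count <- function(radius, h, offset = c(0, 0)) {
  k <- ceiling(radius / h) + 1
  ij <- expand.grid(i = -k:k, j = -k:k)
  sum(((ij$i - offset[1]) * h)^2 + ((ij$j - offset[2]) * h)^2 < radius^2)
}
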