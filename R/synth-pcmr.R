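# Synthetic PC-MR acquisition generator: renders the analytic Womersley
# solution onto a pixel grid, adds calibrated velocity/magnitude noise,
# wraps velocities beyond +/-Venc, and emulates the differential-pressure
# sensor trace. Gating is emulated by sampling the analytic solution at
# n_phases uniform times; there is no k-space simulation.

# run expr with a private RNG stream; the caller's .Random.seed is restored
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sub-pixel placement of the lumen on the image grid
#'
#' Controls where the lumen center falls relative to the pixel lattice and
#' how pixel values are sampled. Offsets are fractions of a pixel in (x, y):
#' `c(0, 0)` puts the lumen center on a pixel center (the alignment of the
#' 37-pixel simulation ROI), `c(0.5, 0.5)` on a pixel corner (the 32-pixel
#' experimental ROI).
#'
#' @param offset length-2 numeric in \[0, 1): lumen-center offset in pixels.
#' @param supersample integer k >= 1; k = 1 samples pixel centers (default,
#'   reproduces the printed pixel counts), k > 1 averages a k x k sub-grid
#'   per pixel (partial-volume rendering).
#' @return object of class `grid_placement`.
#' @export
grid_placement <- function(offset = c(0, 0), supersample = 1L) {
  if (length(offset) != 2 || any(!is.finite(offset)) ||
      any(offset < 0) || any(offset >= 1))
    stop("invalid parameter: offset components must lie in [0, 1)", call. = FALSE)
  if (!is.finite(supersample) || supersample < 1 ||
      supersample != round(supersample))
    stop("invalid parameter: supersample must be an integer >= 1", call. = FALSE)
  structure(list(offset = as.numeric(offset),
                 supersample = as.integer(supersample)),
            class = "grid_placement")
}

#' Gated series of velocity and magnitude images
#'
#' Container for a through-plane PC-MR acquisition: a stack of velocity maps
#' (cm/s) and magnitude maps (dimensionless, lumen 1.0 / background 0.2
#' before noise), one per cardiac phase, with the acquisition metadata and
#' uniform timestamps over one cycle. Arrays are `[ny, nx, n_phases]`
#' (row = y, column = x).
#'
#' @param velocity,magnitude numeric arrays `[ny, nx, n_phases]`.
#' @param acquisition an [acquisition_geometry()].
#' @param timestamps per-phase times, s; strictly increasing, spanning less
#'   than one cycle.
#' @param lumen optional list describing the rendered lumen (center pixel,
#'   offset, radius); carried for provenance.
#' @param seed RNG seed that produced the noise, or NA if noise free.
#' @return object of class `velocity_series`.
#' @export
velocity_series <- function(velocity, magnitude, acquisition, timestamps,
                            lumen = NULL, seed = NA_integer_) {
  stopifnot(inherits(acquisition, "acquisition_geometry"))
  if (!identical(dim(velocity), dim(magnitude)))
    stop("velocity and magnitude shapes differ", call. = FALSE)
  if (length(dim(velocity)) != 3 ||
      dim(velocity)[3] != length(timestamps))
    stop("velocity must be [ny, nx, n_phases] matching timestamps",
         call. = FALSE)
  if (any(diff(timestamps) <= 0) ||
      (max(timestamps) - min(timestamps)) >= acquisition$cycle_period)
    stop("timestamps must be strictly increasing within one cycle",
         call. = FALSE)
  structure(
    list(velocity = velocity, magnitude = magnitude,
         acquisition = acquisition, timestamps = timestamps,
         lumen = lumen, seed = seed),
    class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  d <- dim(x$velocity)
  cat(sprintf(
    "<velocity_series: %dx%d pixels, %d phases, venc %.3g cm/s, %s>\n",
    d[1], d[2], d[3], x$acquisition$venc,
    if (is.na(x$seed)) "noise free" else sprintf("seed %d", x$seed)))
  invisible(x)
}

#' Render a Womersley flow as a synthetic PC-MR series
#'
#' Samples the analytic axial velocity at pixel centers (or a k x k sub-grid
#' mean when supersampling) on the acquisition grid, at `n_phases` uniform
#' times over one cycle. Pixels inside the lumen carry magnitude 1.0, the
#' rest `background_magnitude`; velocity outside the lumen is exactly zero.
#'
#' @param flow an [oscillatory_pipe_flow()]; its period overrides nothing --
#'   the acquisition's `cycle_period` must match it to 1e-9 relative.
#' @param acquisition an [acquisition_geometry()].
#' @param placement a [grid_placement()].
#' @param background_magnitude magnitude outside the lumen (default 0.2, so
#'   the printed 0.60 threshold splits lumen from background).
#' @return a [velocity_series()], noise free.
#' @export
render_series <- function(flow, acquisition, placement = grid_placement(),
                          background_magnitude = 0.2) {
  stopifnot(inherits(flow, "oscillatory_pipe_flow"),
            inherits(acquisition, "acquisition_geometry"),
            inherits(placement, "grid_placement"))
  if (abs(acquisition$cycle_period - flow$period) > 1e-9 * flow$period)
    stop("configuration error: acquisition cycle_period does not match the ",
         "flow period", call. = FALSE)
  n <- acquisition$matrix_size
  h <- acquisition$pixel_spacing
  R <- flow$radius
  ic <- floor(n / 2) + 1  # lumen anchored at the central pixel
  if (R + max(placement$offset) * h >= (min(ic, n - ic) - 1) * h)
    stop("configuration error: lumen larger than grid", call. = FALSE)
  # pixel-center coordinates relative to the lumen center
  x1 <- (seq_len(n) - ic - placement$offset[1]) * h
  y1 <- (seq_len(n) - ic - placement$offset[2]) * h
  xx <- matrix(x1, n, n, byrow = TRUE)
  yy <- matrix(y1, n, n)
  rr <- sqrt(xx^2 + yy^2)
  nph <- acquisition$n_phases
  tk <- (seq_len(nph) - 1) * flow$period / nph
  ph <- exp(1i * flow$angular_frequency * tk)
  vel <- array(0, c(n, n, nph))
  mag <- array(background_magnitude, c(n, n, nph))
  k <- placement$supersample
  if (k == 1L) {
    inside <- rr < R
    prof <- womersley_profile(flow, rr[inside])
    for (p in seq_len(nph)) {
      vp <- matrix(0, n, n)
      vp[inside] <- Re(prof * ph[p])
      vel[, , p] <- vp
      mp <- matrix(background_magnitude, n, n)
      mp[inside] <- 1
      mag[, , p] <- mp
    }
  } else {
    sub <- ((seq_len(k)) - 0.5) / k - 0.5
    touch <- which(rr < R + h, arr.ind = TRUE)  # pixels the lumen can reach
    profsum <- complex(nrow(touch))
    frac <- numeric(nrow(touch))
    for (sx in sub) for (sy in sub) {
      xs <- xx[touch] + sx * h
      ys <- yy[touch] + sy * h
      rs <- sqrt(xs^2 + ys^2)
      ins <- rs < R
      if (any(ins)) {
        profsum[ins] <- profsum[ins] + womersley_profile(flow, rs[ins])
        frac[ins] <- frac[ins] + 1
      }
    }
    profsum <- profsum / k^2
    frac <- frac / k^2
    for (p in seq_len(nph)) {
      vp <- matrix(0, n, n)
      vp[touch] <- Re(profsum * ph[p])
      vel[, , p] <- vp
      mp <- matrix(background_magnitude, n, n)
      mp[touch] <- frac * 1 + (1 - frac) * background_magnitude
      mag[, , p] <- mp
    }
  }
  velocity_series(vel, mag, acquisition, tk,
                  lumen = list(center_pixel = c(ic, ic),
                               offset = placement$offset,
                               radius = R,
                               supersample = k,
                               q0 = womersley_q0(flow),
                               angular_frequency = flow$angular_frequency))
}

# flow amplitude |Qhat| of a solution (q0 under the sin convention)
womersley_q0 <- function(flow) {
  Mod(1i * flow$gradient_amplitude * pi * flow$radius^2 /
        (flow$fluid$density * flow$angular_frequency) * (1 - flow$f_lambda))
}

#' Add calibrated acquisition noise to a series
#'
#' Adds independent zero-mean Gaussian noise to every velocity pixel with
#' standard deviation [velocity_noise_sigma()] (the high-SNR two-point
#' phase-difference result), and Gaussian noise of standard deviation
#' 1/snr to the magnitude. Identical seeds give bit-identical output; the
#' caller's RNG state is left untouched.
#'
#' @param series a [velocity_series()].
#' @param snr magnitude signal-to-noise ratio (> 0).
#' @param seed integer RNG seed.
#' @return a noisy [velocity_series()].
#' @export
add_noise <- function(series, snr, seed) {
  stopifnot(inherits(series, "velocity_series"))
  if (!is.finite(snr) || snr <= 0)
    stop("invalid parameter: snr must be positive", call. = FALSE)
  sv <- velocity_noise_sigma(series$acquisition$venc, snr)
  d <- dim(series$velocity)
  with_local_seed(seed, {
    series$velocity <- series$velocity + array(stats::rnorm(prod(d), 0, sv), d)
    series$magnitude <- series$magnitude +
      array(stats::rnorm(prod(d), 0, 1 / snr), d)
  })
  series$seed <- as.integer(seed)
  series
}

#' Wrap velocities into the encoding range
#'
#' Phase aliasing: each velocity v maps to ((v + venc) mod 2 venc) - venc,
#' so all values end in \[-venc, venc\]; values already inside (-venc, venc\]
#' are unchanged.
#'
#' @param series a [velocity_series()].
#' @return series with wrapped velocities.
#' @export
wrap_velocity <- function(series) {
  stopifnot(inherits(series, "velocity_series"))
  venc <- series$acquisition$venc
  out <- series$velocity > venc | series$velocity <= -venc
  series$velocity[out] <- ((series$velocity[out] + venc) %% (2 * venc)) - venc
  series
}

#' Emulate the differential-pressure sensor trace
#'
#' Tiles a one-cycle pressure waveform (Pa) over `n_cycles` at a high
#' sampling rate (linear interpolation between waveform samples, periodic
#' wrap) and adds Gaussian sensor noise.
#'
#' @param pressure a [waveform()] in Pa.
#' @param sampling_rate sensor sampling rate, Hz (the experiment used 5 kHz).
#' @param n_cycles number of cycles to record.
#' @param noise_sigma sensor noise standard deviation, Pa.
#' @param seed integer RNG seed.
#' @return object of class `sensor_trace`: data.frame with columns
#'   `time_s`, `dp_pa`, attribute `period`.
#' @export
simulate_sensor_trace <- function(pressure, sampling_rate, n_cycles,
                                  noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(pressure, "waveform"))
  period <- pressure$period
  if (sampling_rate * period < 2)
    stop("invalid parameter: need at least 2 samples per cycle", call. = FALSE)
  n <- round(sampling_rate * n_cycles * period)
  t <- (seq_len(n) - 1) / sampling_rate
  # periodic linear interpolation on the phase coordinate
  knots_t <- c(waveform_times(pressure), period)
  knots_v <- c(pressure$values, pressure$values[1])
  v <- stats::approx(knots_t, knots_v, xout = t %% period)$y
  if (noise_sigma > 0)
    v <- with_local_seed(seed, v + stats::rnorm(n, 0, noise_sigma))
  structure(data.frame(time_s = t, dp_pa = v),
            class = c("sensor_trace", "data.frame"), period = period)
}
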