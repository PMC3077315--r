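# Discrete estimators for each term of the integral mass and momentum
# balance on a conduit control volume, from a velocity series and an ROI
# mask. Each estimator follows the physical definition of its term directly:
# pixel sums over the ROI for the surface integrals, a periodic temporal
# derivative of the flow waveform for the inertia, one-sided wall-normal
# differences at the perimeter for the shear.

mask_series_check <- function(series, mask) {
  stopifnot(inherits(series, "velocity_series"), inherits(mask, "roi_mask"))
  if (!identical(dim(series$velocity)[1:2], dim(mask$mask)))
    stop("configuration error: mask does not fit the series grid",
         call. = FALSE)
  if (!any(mask$mask))
    stop("empty-ROI error: mask has no pixels", call. = FALSE)
}

#' Volume flow rate waveform from a velocity series
#'
#' Pixel-sum estimator of the volume flow through the ROI slice of the
#' control surface: Q^k = sum over ROI pixels of v_i^k * S_pixel, one value
#' per cardiac phase. Flow into the phantom is positive (axial sign
#' convention of the geometry, default +1).
#'
#' @param series a [velocity_series()].
#' @param mask an [roi_mask()].
#' @param axial_sign +1 or -1; sign convention for the through-plane axis.
#' @return [waveform()] in cm^3/s.
#' @export
flow_rate <- function(series, mask, axial_sign = 1) {
  mask_series_check(series, mask)
  s_pix <- series$acquisition$pixel_spacing^2
  vals <- apply(series$velocity, 3, function(m) sum(m[mask$mask])) * s_pix
  waveform(axial_sign * vals, series$acquisition$cycle_period, "cm3/s")
}

#' Rate of change of compartment volume from the mass balance
#'
#' For an incompressible fluid the mass balance reduces to
#' dV/dt = sum(inflows) + net production, relating the volume flow crossing
#' the control surface and net CSF production/absorption to the compartment
#' volume change.
#'
#' @param inflows list of [waveform()]s (cm^3/s), positive into the CV.
#' @param net_production net volumetric production rate, cm^3/s (e.g. CSF
#'   production ~0.006 cm^3/s = 0.36 mL/min; 0 in the phantom).
#' @return [waveform()] of dV/dt in cm^3/s.
#' @export
mass_balance_volume_rate <- function(inflows, net_production = 0) {
  if (inherits(inflows, "waveform")) inflows <- list(inflows)
  stopifnot(length(inflows) >= 1)
  do.call(check_same_sampling, inflows)
  vals <- Reduce(`+`, lapply(inflows, `[[`, "values")) + net_production
  waveform(vals, inflows[[1]]$period, "cm3/s")
}

#' Axial momentum inflow across the measured slice
#'
#' Momentum flux carried through the ROI surface:
#' F_M^k = rho * sum(v_i^k)^2 * S_pixel. Reported for the single measured
#' slice (inflow only); in a short conduit the inflow and outflow nominally
#' cancel, so the net term in the balance defaults to zero.
#'
#' @inheritParams flow_rate
#' @param fluid a [fluid_properties()].
#' @return [waveform()] in dyne.
#' @export
momentum_inflow <- function(series, mask, fluid) {
  mask_series_check(series, mask)
  stopifnot(inherits(fluid, "fluid_properties"))
  s_pix <- series$acquisition$pixel_spacing^2
  vals <- fluid$density *
    apply(series$velocity, 3, function(m) sum(m[mask$mask]^2)) * s_pix
  waveform(vals, series$acquisition$cycle_period, "dyne")
}

#' Inertial force from the flow waveform
#'
#' Rate of change of axial momentum in the conduit CV, assuming an axially
#' uniform profile: F_I = rho * L * dQ/dt, with a periodic temporal
#' derivative (central difference default, exact spectral option for the
#' single-harmonic drive).
#'
#' @param flow a [waveform()] in cm^3/s with at least 3 samples.
#' @param fluid a [fluid_properties()].
#' @param geometry a [conduit_geometry()].
#' @param scheme "central" or "spectral".
#' @return [waveform()] in dyne.
#' @export
inertial_force <- function(flow, fluid, geometry,
                           scheme = c("central", "spectral")) {
  stopifnot(inherits(flow, "waveform"), inherits(fluid, "fluid_properties"),
            inherits(geometry, "conduit_geometry"))
  scheme <- match.arg(scheme)
  dq <- periodic_derivative(flow$values, flow$period, scheme)
  waveform(fluid$density * geometry$axial_length * dq, flow$period, "dyne")
}

#' Viscous force on the control surface
#'
#' Integrates the wall shear over the lateral control surface, assuming the
#' profile is axially uniform over the CV length L. At every exposed face of
#' a perimeter pixel (a 4-neighbor outside the mask) the wall-normal
#' velocity gradient is estimated by the one-sided two-point difference
#' toward the interior neighbor across that face, and each face contributes
#' gradient * pixel spacing to the perimeter line integral:
#' F_V^k = -mu * L * sum over faces (v_interior - v_perimeter). The sum is a
#' discrete flux through the staircase boundary, which converges to the
#' true wall-shear integral under grid refinement; the sign opposes the
#' bulk flow. One-sided differences are biased low on grids coarser than
#' the Stokes layer, which is why the simplified pressure estimate excludes
#' this term.
#'
#' @inheritParams momentum_inflow
#' @param geometry a [conduit_geometry()].
#' @return [waveform()] in dyne.
#' @export
viscous_force <- function(series, mask, fluid, geometry) {
  mask_series_check(series, mask)
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(geometry, "conduit_geometry"))
  m <- mask$mask
  n <- dim(m)
  if (nrow(mask$perimeter_pixels) == 0)
    stop("degenerate-mask error: mask has no perimeter", call. = FALSE)
  shift <- function(a, d) {
    out <- array(if (is.logical(a)) FALSE else 0, dim(a))
    sr <- seq_len(n[1]) + d[1]
    sc <- seq_len(n[2]) + d[2]
    okr <- sr >= 1 & sr <= n[1]
    okc <- sc >= 1 & sc <= n[2]
    out[okr, okc, ] <- a[sr[okr], sc[okc], , drop = FALSE]
    out
  }
  m3 <- array(m, c(n, dim(series$velocity)[3]))
  mu <- fluid$dynamic_viscosity
  total <- 0
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    out_nb <- shift(m3, d)       # mask value at pixel + d
    int_nb <- shift(m3, -d)      # mask value at interior side
    exposed <- m3 & !out_nb
    if (any(exposed & !int_nb))
      stop("degenerate-mask error: perimeter pixel without an interior ",
           "4-neighbor across an exposed face", call. = FALSE)
    v_int <- shift(series$velocity, -d)
    contrib <- (v_int - series$velocity) * exposed
    total <- total + apply(contrib, 3, sum)
  }
  waveform(-mu * geometry$axial_length * total,
           series$acquisition$cycle_period, "dyne")
}

#' Axial body force on the control volume
#'
#' Gravity and frame acceleration: F_B = rho * V * (g_axial - a_axial).
#' Zero for the static, horizontal phantom.
#'
#' @param fluid a [fluid_properties()].
#' @param cv_volume control-volume fluid volume, cm^3.
#' @param axial_gravity axial component of gravity, cm/s^2.
#' @param axial_acceleration axial acceleration of the CV frame, cm/s^2.
#' @return force in dyne (scalar).
#' @export
body_force <- function(fluid, cv_volume, axial_gravity = 0,
                       axial_acceleration = 0) {
  stopifnot(inherits(fluid, "fluid_properties"))
  fluid$density * cv_volume * (axial_gravity - axial_acceleration)
}

#' Pressure force on the control volume from the momentum balance
#'
#' Solves the axial momentum balance for the force the pressure field must
#' exert on the CV. In "simplified" mode (high Womersley number, short
#' conduit, horizontal static phantom) the inertial force balances the
#' pressure force: F_P = F_I. In "full" mode every term is kept:
#' F_P = F_I + (momentum outflow - momentum inflow) - F_V - F_B, where F_V
#' is the (negative, drag) viscous force of [viscous_force()] so -F_V adds
#' the friction the pressure must overcome.
#'
#' @param inertial [waveform()] from [inertial_force()].
#' @param mode "simplified" or "full".
#' @param momentum_in,momentum_out inflow/outflow momentum waveforms (dyne);
#'   both required in full mode.
#' @param viscous viscous-force waveform (dyne); required in full mode.
#' @param body scalar body force, dyne (default 0).
#' @return [waveform()] in dyne.
#' @export
pressure_force_cv <- function(inertial, mode = c("simplified", "full"),
                              momentum_in = NULL, momentum_out = NULL,
                              viscous = NULL, body = 0) {
  stopifnot(inherits(inertial, "waveform"))
  mode <- match.arg(mode)
  if (mode == "simplified")
    return(waveform(inertial$values, inertial$period, "dyne"))
  if (is.null(momentum_in) || is.null(momentum_out) || is.null(viscous))
    stop("configuration error: full mode needs momentum_in, momentum_out ",
         "and viscous waveforms", call. = FALSE)
  check_same_sampling(inertial, momentum_in, momentum_out, viscous)
  waveform(inertial$values + (momentum_out$values - momentum_in$values) -
             viscous$values - body,
           inertial$period, "dyne")
}

#' Urchuk-Plewes per-pixel pressure-gradient estimator
#'
#' The published Navier-Stokes comparator: at every ROI pixel whose full
#' 5-point spatial stencil lies inside the ROI, the driving pressure
#' gradient is estimated as -dp/dz = rho dv/dt - mu lap(v) (periodic central
#' difference in time, 5-point Laplacian in plane), split into inertial and
#' viscous contributions; the per-pixel estimates are averaged over those
#' interior pixels and multiplied by S L to give a force comparable to the
#' CV estimate. Boundary pixels are excluded rather than extrapolating wall
#' values.
#'
#' @inheritParams momentum_inflow
#' @param geometry a [conduit_geometry()].
#' @return list with `gradient`, `inertial_part`, `viscous_part`
#'   ([waveform()]s, Pa/cm), `force`, `force_inertial`, `force_viscous`
#'   ([waveform()]s, dyne), and `n_stencil_pixels`.
#' @export
urchuk_plewes <- function(series, mask, fluid, geometry) {
  mask_series_check(series, mask)
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(geometry, "conduit_geometry"))
  m <- mask$mask
  n <- dim(m)
  pad <- matrix(FALSE, n[1] + 2, n[2] + 2)
  pad[2:(n[1] + 1), 2:(n[2] + 1)] <- m
  interior <- m & pad[1:n[1], 2:(n[2] + 1)] & pad[3:(n[1] + 2), 2:(n[2] + 1)] &
    pad[2:(n[1] + 1), 1:n[2]] & pad[2:(n[1] + 1), 3:(n[2] + 2)]
  if (!any(interior))
    stop("degenerate-ROI error: no pixel with a full interior stencil",
         call. = FALSE)
  h <- series$acquisition$pixel_spacing
  nph <- dim(series$velocity)[3]
  period <- series$acquisition$cycle_period
  dt <- period / nph
  rho <- fluid$density
  mu <- fluid$dynamic_viscosity
  inert <- visc <- numeric(nph)
  idx <- which(interior, arr.ind = TRUE)
  up <- cbind(idx[, 1] - 1, idx[, 2]); dn <- cbind(idx[, 1] + 1, idx[, 2])
  lf <- cbind(idx[, 1], idx[, 2] - 1); rt <- cbind(idx[, 1], idx[, 2] + 1)
  for (k in seq_len(nph)) {
    kp <- k %% nph + 1
    km <- (k - 2) %% nph + 1
    vk <- series$velocity[, , k]
    dvdt <- (series$velocity[, , kp][idx] - series$velocity[, , km][idx]) /
      (2 * dt)
    lap <- (vk[up] + vk[dn] + vk[lf] + vk[rt] - 4 * vk[idx]) / h^2
    inert[k] <- mean(rho * dvdt)
    visc[k] <- mean(-mu * lap)
  }
  sl <- geometry$cross_section_area * geometry$axial_length
  list(
    gradient = waveform(dyne_cm3_to_pa_cm(inert + visc), period, "Pa/cm"),
    inertial_part = waveform(dyne_cm3_to_pa_cm(inert), period, "Pa/cm"),
    viscous_part = waveform(dyne_cm3_to_pa_cm(visc), period, "Pa/cm"),
    force = waveform((inert + visc) * sl, period, "dyne"),
    force_inertial = waveform(inert * sl, period, "dyne"),
    force_viscous = waveform(visc * sl, period, "dyne"),
    n_stencil_pixels = sum(interior))
}

#' Propagate velocity noise into flow and force uncertainty
#'
#' Independent Gaussian pixel noise of standard deviation
#' [velocity_noise_sigma()] propagates into the pixel-sum flow estimate as
#' sigma_Q = sigma_v * S_pixel * sqrt(N), and through the temporal
#' derivative into the inertial/pressure force as
#' sigma_F = rho * L * sigma_Q * gain, where the derivative noise gain is
#' 1/(sqrt(2) dt) for the periodic central difference and the rms of the
#' spectral multipliers |i w_m| for spectral differentiation.
#'
#' @param acquisition an [acquisition_geometry()].
#' @param snr magnitude signal-to-noise ratio.
#' @param mask an [roi_mask()].
#' @param fluid a [fluid_properties()].
#' @param geometry a [conduit_geometry()].
#' @param scheme "central" or "spectral".
#' @return object of class `uncertainty_report`: `sigma_v` (cm/s),
#'   `sigma_q` (cm^3/s), `sigma_inertial` (dyne), `notes`.
#' @export
propagate_uncertainty <- function(acquisition, snr, mask, fluid, geometry,
                                  scheme = c("central", "spectral")) {
  stopifnot(inherits(acquisition, "acquisition_geometry"),
            inherits(mask, "roi_mask"),
            inherits(fluid, "fluid_properties"),
            inherits(geometry, "conduit_geometry"))
  scheme <- match.arg(scheme)
  sigma_v <- velocity_noise_sigma(acquisition$venc, snr)
  sigma_q <- sigma_v * acquisition$pixel_spacing^2 * sqrt(mask$pixel_count)
  n <- acquisition$n_phases
  dt <- acquisition$cycle_period / n
  gain <- if (scheme == "central") {
    1 / (sqrt(2) * dt)
  } else {
    m <- c(0:(n %/% 2), if (n > 1) -((n - (n %/% 2) - 1):1))
    if (n %% 2 == 0) m[n %/% 2 + 1] <- 0
    sqrt(mean((2 * pi * m / acquisition$cycle_period)^2))
  }
  structure(
    list(sigma_v = sigma_v, sigma_q = sigma_q,
         sigma_inertial = fluid$density * geometry$axial_length * sigma_q * gain,
         notes = sprintf(
           "independent pixel noise; N = %d, %s-difference derivative gain %.4g 1/s",
           mask$pixel_count, scheme, gain)),
    class = "uncertainty_report")
}

#' Full momentum budget of a conduit control volume
#'
#' Driver assembling every estimator: flow, inertial force, single-surface
#' momentum inflow, viscous force, body force, the CV pressure force
#' (simplified mode equates it to the inertial force), its Urchuk-Plewes
#' counterpart, and the pressure gradient in Pa/cm.
#'
#' @inheritParams momentum_inflow
#' @param geometry a [conduit_geometry()].
#' @param scheme temporal-derivative scheme, "central" or "spectral".
#' @param mode "simplified" (default) or "full"; full mode uses the measured
#'   slice for both momentum surfaces (net zero, the short-conduit
#'   assumption) and subtracts the viscous and body terms.
#' @param snr if not NULL, attach a [propagate_uncertainty()] report.
#' @param axial_gravity,axial_acceleration body-force components, cm/s^2.
#' @return object of class `momentum_budget`.
#' @export
momentum_budget <- function(series, mask, fluid, geometry,
                            scheme = c("central", "spectral"),
                            mode = c("simplified", "full"),
                            snr = NULL,
                            axial_gravity = 0, axial_acceleration = 0) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  q <- flow_rate(series, mask)
  fi <- inertial_force(q, fluid, geometry, scheme)
  fm <- momentum_inflow(series, mask, fluid)
  fv <- viscous_force(series, mask, fluid, geometry)
  fb <- body_force(fluid,
                   geometry$cross_section_area * geometry$axial_length,
                   axial_gravity, axial_acceleration)
  fp <- if (mode == "simplified") {
    pressure_force_cv(fi, "simplified")
  } else {
    pressure_force_cv(fi, "full", momentum_in = fm, momentum_out = fm,
                      viscous = fv, body = fb)
  }
  up <- urchuk_plewes(series, mask, fluid, geometry)
  structure(
    list(flow = q,
         inertial_force = fi,
         momentum_inflow = fm,
         viscous_force = fv,
         body_force = fb,
         pressure_force_cv = fp,
         pressure_gradient = waveform(force_to_gradient(fp$values, geometry),
                                      fp$period, "Pa/cm"),
         up = up,
         uncertainty = if (!is.null(snr))
           propagate_uncertainty(series$acquisition, snr, mask, fluid,
                                 geometry, scheme),
         mode = mode, scheme = scheme,
         geometry = geometry, fluid = fluid),
    class = "momentum_budget")
}

#' @export
print.momentum_budget <- function(x, ...) {
  amp <- function(w) (max(w$values) - min(w$values)) / 2
  cat(sprintf(
    paste0("<momentum_budget (%s, %s):\n",
           "  flow amplitude        %8.3g mL/min\n",
           "  inertial force        %8.3g dyne\n",
           "  momentum inflow       %8.3g dyne\n",
           "  viscous force         %8.3g dyne\n",
           "  pressure force (CV)   %8.3g dyne\n",
           "  pressure gradient     %8.3g Pa/cm>\n"),
    x$mode, x$scheme, cm3s_to_ml_min(amp(x$flow)), amp(x$inertial_force),
    amp(x$momentum_inflow), amp(x$viscous_force),
    amp(x$pressure_force_cv), amp(x$pressure_gradient)))
  invisible(x)
}
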