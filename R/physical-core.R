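#' Fluid properties in CGS units
#'
#' Bundles mass density (g/cm^3) and dynamic viscosity (poise,
#' g cm^-1 s^-1); the kinematic viscosity nu = mu/rho (cm^2/s) is derived
#' and stored for convenience.
#'
#' @param density mass density, g/cm^3. Must be positive.
#' @param dynamic_viscosity dynamic viscosity, poise. Must be positive.
#' @return an object of class `fluid_properties` with fields `density`,
#'   `dynamic_viscosity` and `kinematic_viscosity`.
#' @examples
#' water()
#' @export
fluid_properties <- function(density, dynamic_viscosity) {
  if (!is.finite(density) || density <= 0)
    stop("invalid parameter: density must be a positive number", call. = FALSE)
  if (!is.finite(dynamic_viscosity) || dynamic_viscosity <= 0)
    stop("invalid parameter: dynamic_viscosity must be a positive number",
         call. = FALSE)
  structure(
    list(density = density,
         dynamic_viscosity = dynamic_viscosity,
         kinematic_viscosity = dynamic_viscosity / density),
    class = "fluid_properties")
}

#' @rdname fluid_properties
#' @details `water()` returns the experimental fluid used throughout: water at
#'   room temperature, rho = 1 g/cm^3, mu = 0.01 poise (nu = 0.01 cm^2/s).
#' @export
water <- function() fluid_properties(density = 1, dynamic_viscosity = 0.01)

#' Conduit control-volume geometry
#'
#' Describes a straight cylindrical control volume (CV): the flow passage
#' diameter, the axial length between the pressure taps, and the
#' cross-section area (defaults to pi D^2/4).
#'
#' @param diameter lumen diameter, cm.
#' @param axial_length axial CV length between pressure taps, cm.
#' @param cross_section_area flow cross-section, cm^2; default `pi*diameter^2/4`.
#' @param axial_sign +1 if positive velocity means flow into the phantom
#'   (the convention used throughout), -1 to flip.
#' @return object of class `conduit_geometry`.
#' @export
conduit_geometry <- function(diameter, axial_length,
                             cross_section_area = pi * diameter^2 / 4,
                             axial_sign = 1) {
  vals <- c(diameter = diameter, axial_length = axial_length,
            cross_section_area = cross_section_area)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid parameter: conduit geometry lengths/areas must be positive",
         call. = FALSE)
  if (!axial_sign %in% c(-1, 1))
    stop("invalid parameter: axial_sign must be +1 or -1", call. = FALSE)
  structure(
    list(diameter = diameter, axial_length = axial_length,
         cross_section_area = cross_section_area, axial_sign = axial_sign),
    class = "conduit_geometry")
}

#' PC-MR acquisition geometry and timing
#'
#' @param field_of_view in-plane field of view, cm (square matrix assumed).
#' @param matrix_size image matrix size (pixels per side), integer >= 1.
#' @param slice_thickness slice thickness, cm.
#' @param n_phases number of reconstructed cardiac phases, >= 3.
#' @param cycle_period cardiac/pump cycle period, s.
#' @param venc velocity-encoding value, cm/s; velocities map to image phase
#'   in (-pi, pi] so measured values lie in (-venc, venc].
#' @return object of class `acquisition_geometry`; `pixel_spacing` is
#'   `field_of_view / matrix_size`.
#' @export
acquisition_geometry <- function(field_of_view, matrix_size, slice_thickness,
                                 n_phases, cycle_period, venc) {
  if (!is.finite(field_of_view) || field_of_view <= 0)
    stop("invalid parameter: field_of_view must be positive", call. = FALSE)
  if (!is.finite(matrix_size) || matrix_size < 1 ||
      matrix_size != round(matrix_size))
    stop("invalid parameter: matrix_size must be a positive integer",
         call. = FALSE)
  if (!is.finite(n_phases) || n_phases < 3 || n_phases != round(n_phases))
    stop("invalid parameter: n_phases must be an integer >= 3", call. = FALSE)
  if (!is.finite(cycle_period) || cycle_period <= 0)
    stop("invalid parameter: cycle_period must be positive", call. = FALSE)
  if (!is.finite(venc) || venc <= 0)
    stop("invalid parameter: venc must be positive", call. = FALSE)
  if (!is.finite(slice_thickness) || slice_thickness <= 0)
    stop("invalid parameter: slice_thickness must be positive", call. = FALSE)
  structure(
    list(field_of_view = field_of_view,
         matrix_size = as.integer(matrix_size),
         pixel_spacing = field_of_view / matrix_size,
         slice_thickness = slice_thickness,
         n_phases = as.integer(n_phases),
         cycle_period = cycle_period,
         venc = venc),
    class = "acquisition_geometry")
}

#' Reynolds number from the peak volume flow rate
#'
#' Defined from the peak flow rate: Re = (Q_max/S) * D / nu, i.e. the mean
#' velocity at peak flow times diameter over kinematic viscosity.
#'
#' @param q_max peak volume flow rate, cm^3/s (>= 0).
#' @param geometry a [conduit_geometry()].
#' @param fluid a [fluid_properties()].
#' @return dimensionless Reynolds number.
#' @examples
#' reynolds_from_peak_flow(ml_min_to_cm3s(46), conduit_geometry(1.27, 3.81), water())
#' @export
reynolds_from_peak_flow <- function(q_max, geometry, fluid) {
  stopifnot(inherits(geometry, "conduit_geometry"),
            inherits(fluid, "fluid_properties"))
  if (!is.finite(q_max) || q_max < 0)
    stop("invalid parameter: q_max must be >= 0", call. = FALSE)
  (q_max / geometry$cross_section_area) * geometry$diameter /
    fluid$kinematic_viscosity
}

#' Peak volume flow rate implied by a Reynolds number
#'
#' Inverse of [reynolds_from_peak_flow()]: Q_max = Re * nu * S / D.
#'
#' @param re dimensionless Reynolds number (>= 0).
#' @inheritParams reynolds_from_peak_flow
#' @return peak volume flow rate, cm^3/s.
#' @export
peak_flow_from_reynolds <- function(re, geometry, fluid) {
  stopifnot(inherits(geometry, "conduit_geometry"),
            inherits(fluid, "fluid_properties"))
  if (!is.finite(re) || re < 0)
    stop("invalid parameter: re must be >= 0", call. = FALSE)
  re * fluid$kinematic_viscosity * geometry$cross_section_area /
    geometry$diameter
}

#' Womersley number
#'
#' alpha = (D/2) sqrt(omega/nu) with omega = 2 pi f; the ratio of transient
#' inertial to viscous forces in oscillatory flow. alpha >~ 2.5 marks the
#' inertia-dominated regime with a flat core velocity profile.
#'
#' @param geometry a [conduit_geometry()].
#' @param frequency oscillation frequency, Hz (> 0).
#' @param fluid a [fluid_properties()].
#' @return dimensionless Womersley number.
#' @examples
#' womersley_number(conduit_geometry(1.27, 3.81), 1, water())
#' @export
womersley_number <- function(geometry, frequency, fluid) {
  stopifnot(inherits(geometry, "conduit_geometry"),
            inherits(fluid, "fluid_properties"))
  if (!is.finite(frequency) || frequency <= 0)
    stop("invalid parameter: frequency must be positive", call. = FALSE)
  (geometry$diameter / 2) *
    sqrt(2 * pi * frequency / fluid$kinematic_viscosity)
}

#' Pixel spacing from field of view and matrix size
#'
#' @param field_of_view field of view, cm.
#' @param matrix_size matrix size, integer >= 1.
#' @return pixel spacing, cm.
#' @export
pixel_spacing <- function(field_of_view, matrix_size) {
  if (!is.finite(matrix_size) || matrix_size < 1)
    stop("invalid parameter: matrix_size must be >= 1", call. = FALSE)
  field_of_view / matrix_size
}

#' Convert an axial force on the CV to a pressure gradient
#'
#' Divides a force (dyne) by the CV volume S*L (cm^3) and converts
#' dyne/cm^3 to Pa/cm (factor 0.1).
#'
#' @param force axial force, dyne (may be a vector or waveform values).
#' @param geometry a [conduit_geometry()].
#' @return pressure gradient, Pa/cm.
#' @export
force_to_gradient <- function(force, geometry) {
  stopifnot(inherits(geometry, "conduit_geometry"))
  dyne_cm3_to_pa_cm(
    force / (geometry$cross_section_area * geometry$axial_length))
}

#' Velocity noise standard deviation of two-point PC-MR images
#'
#' The standard high-SNR relation for two-point phase-difference velocity
#' maps: sigma_v = sqrt(2) * venc / (pi * SNR). With venc = 20 cm/s and
#' SNR = 25 this gives 0.36 cm/s.
#'
#' @param venc velocity-encoding value, cm/s (> 0).
#' @param snr magnitude signal-to-noise ratio (> 0).
#' @return velocity noise standard deviation, cm/s.
#' @export
velocity_noise_sigma <- function(venc, snr) {
  if (!is.finite(venc) || venc <= 0)
    stop("invalid parameter: venc must be positive", call. = FALSE)
  if (!is.finite(snr) || snr <= 0)
    stop("invalid parameter: snr must be positive", call. = FALSE)
  sqrt(2) * venc / (pi * snr)
}
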