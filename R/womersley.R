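#' Exact Womersley solution for oscillatory pipe flow
#'
#' Fully developed, sinusoidally driven laminar flow of an incompressible
#' Newtonian fluid in a rigid circular pipe. With the complex gradient
#' amplitude K defined by dp/dz(t) = Re\[K exp(i w t)\] (dyne/cm^3), the
#' axial velocity is
#'
#'   w(r, t) = Re\[ (i K / (rho w)) (1 - J0(L r/R)/J0(L)) exp(i w t) \]
#'
#' with L = i^{3/2} alpha, alpha = R sqrt(w/nu) the Womersley number, and
#' the branch i^{3/2} = exp(i 3 pi/4). The complex flow amplitude follows by
#' integrating over the cross-section:
#'
#'   Qhat = (i K pi R^2 / (rho w)) (1 - 2 J1(L) / (L J0(L)))
#'
#' @param radius pipe radius R, cm.
#' @param angular_frequency omega, rad/s.
#' @param fluid a [fluid_properties()].
#' @param gradient_amplitude complex K, dyne/cm^3.
#' @return object of class `oscillatory_pipe_flow` with fields `radius`,
#'   `angular_frequency`, `fluid`, `gradient_amplitude`, `womersley_alpha`,
#'   `period`, and cached Bessel quantities.
#' @seealso [womersley_from_flow_amplitude()] to construct from a flow
#'   amplitude instead of a gradient amplitude.
#' @export
oscillatory_pipe_flow <- function(radius, angular_frequency, fluid,
                                  gradient_amplitude) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!is.finite(radius) || radius <= 0)
    stop("invalid parameter: radius must be positive", call. = FALSE)
  if (!is.finite(angular_frequency) || angular_frequency <= 0)
    stop("invalid parameter: angular_frequency must be positive", call. = FALSE)
  alpha <- radius * sqrt(angular_frequency / fluid$kinematic_viscosity)
  lam <- complex(modulus = alpha, argument = 3 * pi / 4)  # i^{3/2} alpha
  j0 <- besselJ_complex(lam, 0)
  Fa <- 2 * besselJ_complex(lam, 1) / (lam * j0)
  structure(
    list(radius = radius,
         angular_frequency = angular_frequency,
         period = 2 * pi / angular_frequency,
         fluid = fluid,
         gradient_amplitude = as.complex(gradient_amplitude),
         womersley_alpha = alpha,
         lambda = lam,
         j0_lambda = j0,
         f_lambda = Fa),
    class = "oscillatory_pipe_flow")
}

#' Womersley solution with a prescribed flow-waveform amplitude
#'
#' Returns the solution whose volume-flow waveform is Q(t) = q0 sin(w t)
#' (flow into the phantom positive), i.e. Qhat = -i q0, which fixes the
#' gradient amplitude to K = -q0 rho w / (pi R^2 (1 - F(L))) with
#' F(L) = 2 J1(L) / (L J0(L)).
#'
#' @param q0 flow amplitude, cm^3/s (>= 0).
#' @inheritParams oscillatory_pipe_flow
#' @return an [oscillatory_pipe_flow()].
#' @examples
#' flow <- womersley_from_flow_amplitude(ml_min_to_cm3s(46), 0.635,
#'                                       2 * pi, water())
#' flow$womersley_alpha
#' @export
womersley_from_flow_amplitude <- function(q0, radius, angular_frequency, fluid) {
  if (!is.finite(q0) || q0 < 0)
    stop("invalid parameter: q0 must be >= 0", call. = FALSE)
  flow <- oscillatory_pipe_flow(radius, angular_frequency, fluid, 0i)
  flow$gradient_amplitude <-
    -q0 * fluid$density * angular_frequency /
    (pi * radius^2 * (1 - flow$f_lambda))
  flow
}

# complex velocity profile what(r): w(r,t) = Re[what(r) exp(i w t)]
womersley_profile <- function(flow, r) {
  if (any(abs(r) > flow$radius * (1 + 1e-12)))
    stop("domain error: |r| exceeds the pipe radius", call. = FALSE)
  r <- pmin(abs(r), flow$radius)  # axisymmetric; clamp rounding at the wall
  (1i * flow$gradient_amplitude / (flow$fluid$density * flow$angular_frequency)) *
    (1 - besselJ_complex(flow$lambda * r / flow$radius, 0) / flow$j0_lambda)
}

#' Axial velocity of a Womersley flow
#'
#' @param flow an [oscillatory_pipe_flow()].
#' @param r radial coordinate(s), cm; |r| must not exceed the radius
#'   (the profile is axisymmetric).
#' @param t time(s), s. `r` and `t` are recycled to a common length.
#' @return axial velocity, cm/s.
#' @export
womersley_velocity <- function(flow, r, t) {
  stopifnot(inherits(flow, "oscillatory_pipe_flow"))
  Re(womersley_profile(flow, r) * exp(1i * flow$angular_frequency * t))
}

#' Volume flow rate of a Womersley flow
#'
#' `womersley_flow_rate()` evaluates Q(t) at arbitrary times;
#' `womersley_flow_waveform()` samples one cycle uniformly into a
#' [waveform()] (cm^3/s).
#'
#' @inheritParams womersley_velocity
#' @param times times, s.
#' @export
womersley_flow_rate <- function(flow, times) {
  stopifnot(inherits(flow, "oscillatory_pipe_flow"))
  qhat <- 1i * flow$gradient_amplitude * pi * flow$radius^2 /
    (flow$fluid$density * flow$angular_frequency) * (1 - flow$f_lambda)
  Re(qhat * exp(1i * flow$angular_frequency * times))
}

#' @rdname womersley_flow_rate
#' @param n_samples samples per cycle.
#' @export
womersley_flow_waveform <- function(flow, n_samples) {
  tk <- (seq_len(n_samples) - 1) * flow$period / n_samples
  waveform(womersley_flow_rate(flow, tk), flow$period, "cm3/s")
}

#' Analytic pressure force on a conduit control volume
#'
#' The axial force the pressure field exerts on the CV occupied by the flow:
#' F_p(t) = -Re\[K exp(i w t)\] S L (dyne); positive force accelerates fluid
#' in the +axial direction. Serves as the ground-truth oracle for the
#' image-derived estimators.
#'
#' @param flow an [oscillatory_pipe_flow()].
#' @param geometry a [conduit_geometry()] whose radius must match the flow's
#'   (relative tolerance 1e-6).
#' @param n_samples samples per cycle.
#' @return [waveform()] in dyne.
#' @export
womersley_pressure_force_waveform <- function(flow, geometry, n_samples) {
  stopifnot(inherits(flow, "oscillatory_pipe_flow"),
            inherits(geometry, "conduit_geometry"))
  if (abs(geometry$diameter / 2 - flow$radius) > 1e-6 * flow$radius)
    stop("configuration error: conduit radius does not match the flow solution",
         call. = FALSE)
  tk <- (seq_len(n_samples) - 1) * flow$period / n_samples
  vals <- -Re(flow$gradient_amplitude * exp(1i * flow$angular_frequency * tk)) *
    geometry$cross_section_area * geometry$axial_length
  waveform(vals, flow$period, "dyne")
}
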