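# All internal computation is CGS (cm, g, s, dyne, poise); SI enters and
# leaves only through the conversion helpers below, so every round trip is a
# single exact multiplication.

#' Unit conversions between CGS and reporting units
#'
#' The package computes in CGS throughout. These helpers convert at the
#' reporting boundary: pressure (Pa vs dyne/cm^2), pressure gradient
#' (Pa/cm vs dyne/cm^3) and volume flow (mL/min vs cm^3/s). Each is a single
#' multiplication, so `pa_to_dyne_cm2(dyne_cm2_to_pa(x))` is exact to machine
#' precision.
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
dyne_cm2_to_pa <- function(x) 0.1 * x

#' @rdname units
#' @export
pa_to_dyne_cm2 <- function(x) 10 * x

#' @rdname units
#' @export
dyne_cm3_to_pa_cm <- function(x) 0.1 * x

#' @rdname units
#' @export
pa_cm_to_dyne_cm3 <- function(x) 10 * x

#' @rdname units
#' @export
cm3s_to_ml_min <- function(x) 60 * x

#' @rdname units
#' @export
ml_min_to_cm3s <- function(x) x / 60
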