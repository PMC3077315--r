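#' One-cycle periodic waveform
#'
#' A uniformly sampled, periodic signal over a single cycle: sample k
#' (1-based) is taken at t_k = (k-1) * period / n_samples, and index
#' arithmetic is modulo n_samples. Units are carried as a label
#' ("cm3/s", "dyne", "Pa", "Pa/cm", ...).
#'
#' @param values numeric samples over one cycle.
#' @param period cycle period, s.
#' @param units unit label.
#' @return object of class `waveform` with fields `values`, `period`,
#'   `units`, `n_samples`.
#' @export
waveform <- function(values, period, units = "") {
  if (!is.numeric(values) || length(values) < 1 || any(!is.finite(values)))
    stop("waveform values must be finite numerics", call. = FALSE)
  if (!is.finite(period) || period <= 0)
    stop("waveform period must be positive", call. = FALSE)
  structure(
    list(values = as.numeric(values), period = period, units = units,
         n_samples = length(values)),
    class = "waveform")
}

#' @rdname waveform
#' @param wf a `waveform`.
#' @return `waveform_times()`: the sample times t_k = (k-1) * period / n.
#' @export
waveform_times <- function(wf) {
  stopifnot(inherits(wf, "waveform"))
  (seq_len(wf$n_samples) - 1) * wf$period / wf$n_samples
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples over %.4g s [%s], range [%.4g, %.4g]>\n",
              x$n_samples, x$period, x$units,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.waveform <- function(x, ...) {
  data.frame(time_s = waveform_times(x), value = x$values,
             units = x$units, stringsAsFactors = FALSE)
}

# shared-sampling guard used by every multi-waveform operation
check_same_sampling <- function(...) {
  wfs <- list(...)
  ns <- vapply(wfs, function(w) w$n_samples, integer(1))
  ps <- vapply(wfs, function(w) w$period, numeric(1))
  if (length(unique(ns)) != 1 ||
      diff(range(ps)) > 1e-9 * max(ps))
    stop("configuration error: waveforms do not share sampling ",
         "(n_samples/period mismatch)", call. = FALSE)
  invisible(TRUE)
}

#' Periodic temporal derivative of a sampled cycle
#'
#' Derivative of a one-cycle periodic sample sequence, either by
#' second-order central differences with wrap-around indexing (default;
#' attenuates a single harmonic by sin(w dt)/(w dt)) or by exact spectral
#' (FFT) differentiation, which is exact for band-limited signals such as
#' the single-harmonic pump waveform.
#'
#' @param values samples over one cycle.
#' @param period cycle period, s.
#' @param scheme "central" or "spectral".
#' @return derivative samples, same length.
#' @export
periodic_derivative <- function(values, period, scheme = c("central", "spectral")) {
  scheme <- match.arg(scheme)
  n <- length(values)
  if (n < 3)
    stop("insufficient sampling: need at least 3 samples per cycle",
         call. = FALSE)
  dt <- period / n
  if (scheme == "central") {
    (values[c(2:n, 1)] - values[c(n, 1:(n - 1))]) / (2 * dt)
  } else {
    m <- c(0:(n %/% 2), if (n > 1) -((n - (n %/% 2) - 1):1))
    if (n %% 2 == 0) m[n %/% 2 + 1] <- 0  # drop the unpaired Nyquist mode
    vh <- stats::fft(values)
    Re(stats::fft(vh * 1i * (2 * pi * m / period), inverse = TRUE)) / n
  }
}
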