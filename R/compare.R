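# Waveform statistics used to reduce and compare cycles: phase averaging of
# long sensor traces, ensemble averaging across experiments, sinusoid
# fitting at the known drive frequency, and normalized rms deviation.

#' Phase-average a long periodic trace into one cycle
#'
#' Assigns every sample of a high-rate trace to one of `n_bins` uniform
#' phase bins modulo the period and returns the bin means as a one-cycle
#' waveform. The incomplete trailing cycle is discarded. Bin k covers phase
#' \[(k-1), k) * period / n_bins; the returned waveform sample k is the mean
#' of its bin, so a noise-free trace sampled on a grid that divides the
#' period is recovered exactly.
#'
#' @param trace a `sensor_trace` (or data.frame with `time_s` and a value
#'   column as its second column).
#' @param period cycle period, s.
#' @param n_bins number of phase bins.
#' @param units unit label of the result (default "Pa").
#' @return [waveform()] of bin means.
#' @export
phase_average <- function(trace, period, n_bins, units = "Pa") {
  t <- trace[[1]]
  v <- trace[[2]]
  if (length(t) < 2) stop("insufficient data: empty trace", call. = FALSE)
  dt <- t[2] - t[1]
  n_complete <- floor((max(t) - min(t) + dt) / period)
  if (n_complete < 2)
    stop("insufficient data: trace spans fewer than 2 full periods",
         call. = FALSE)
  keep <- t - min(t) < n_complete * period
  t <- t[keep]; v <- v[keep]
  # snap phases lying within rounding error of a bin edge onto it, so a
  # sampling grid commensurate with the period bins deterministically
  u <- ((t - min(t)) %% period) / period * n_bins
  bin <- floor(u + 1e-9) + 1
  bin[bin > n_bins] <- 1L  # the wrap point belongs to the first bin
  vals <- vapply(split(v, factor(bin, levels = seq_len(n_bins))),
                 mean, numeric(1))
  if (any(is.na(vals)))
    stop("insufficient data: empty phase bin; lower n_bins", call. = FALSE)
  waveform(unname(vals), period, units)
}

#' Ensemble average of repeated cycle waveforms
#'
#' Pointwise mean and sample standard deviation across experiments, as used
#' to combine the six phase-averaged sensor runs into one mean pressure
#' waveform.
#'
#' @param waveforms list of [waveform()]s sharing sampling.
#' @return list with `mean` and `pointwise_std` waveforms.
#' @export
ensemble_average <- function(waveforms) {
  stopifnot(length(waveforms) >= 1)
  do.call(check_same_sampling, waveforms)
  mat <- vapply(waveforms, `[[`, numeric(waveforms[[1]]$n_samples), "values")
  mat <- matrix(mat, nrow = waveforms[[1]]$n_samples)
  m <- rowMeans(mat)
  s <- if (ncol(mat) > 1) apply(mat, 1, stats::sd) else rep(0, nrow(mat))
  list(mean = waveform(m, waveforms[[1]]$period, waveforms[[1]]$units),
       pointwise_std = waveform(s, waveforms[[1]]$period,
                                waveforms[[1]]$units))
}

#' Fit a sinusoid of known frequency to a waveform
#'
#' Linear least squares on the basis \{sin(wt), cos(wt), 1\}:
#' fit(t) = amplitude * sin(w t + phase) + offset.
#'
#' @param wf a [waveform()] with >= 3 samples.
#' @param frequency known frequency, Hz.
#' @return list with `amplitude`, `phase` (rad), `offset`.
#' @export
fit_sinusoid <- function(wf, frequency) {
  stopifnot(inherits(wf, "waveform"))
  if (wf$n_samples < 3)
    stop("insufficient sampling: need at least 3 samples", call. = FALSE)
  w <- 2 * pi * frequency
  t <- waveform_times(wf)
  X <- cbind(sin(w * t), cos(w * t), 1)
  if (qr(X)$rank < 3)
    stop("rank error: degenerate sampling for sinusoid fit", call. = FALSE)
  cf <- qr.solve(X, wf$values)
  list(amplitude = sqrt(cf[1]^2 + cf[2]^2),
       phase = atan2(cf[2], cf[1]),
       offset = cf[3])
}

#' Normalized rms deviation between two waveforms
#'
#' rms(test - reference), normalized either by the range (max - min) of the
#' reference (the convention stated for the flow-vs-fit comparison) or by
#' its peak magnitude max|reference| (consistent with the printed pressure
#' force comparison). Both conventions are exposed and named; neither is
#' silently preferred.
#'
#' @param test,reference [waveform()]s sharing sampling.
#' @param normalization "range" (default) or "amplitude".
#' @return list with `absolute` (units of the waveforms), `percent`, and
#'   `normalization`.
#' @export
normalized_rms_deviation <- function(test, reference,
                                     normalization = c("range", "amplitude")) {
  stopifnot(inherits(test, "waveform"), inherits(reference, "waveform"))
  normalization <- match.arg(normalization)
  check_same_sampling(test, reference)
  rms <- sqrt(mean((test$values - reference$values)^2))
  denom <- if (normalization == "range") {
    diff(range(reference$values))
  } else {
    max(abs(reference$values))
  }
  if (denom == 0)
    stop(if (normalization == "range") "zero-range error: constant reference"
         else "zero-amplitude error: zero reference", call. = FALSE)
  list(absolute = rms, percent = 100 * rms / denom,
       normalization = normalization)
}
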