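#' Filter configuration
#'
#' Settings for the two retained preprocessing filters, applied in order:
#' low-pass amplitude-controlled filtering (clip excursions beyond
#' `amplitude_clamp` from a running-median baseline, then a first-order
#' low-pass recursion at `lowpass_cutoff_hz`), followed by sliding-window
#' median filtering.
#'
#' @param lowpass_cutoff_hz Low-pass cutoff in Hz; must lie below the Nyquist
#'   frequency of the trace it is applied to. Default 15 Hz: compression
#'   energy at 100--120/min sits below ~10 Hz including the first harmonics.
#' @param amplitude_clamp Maximum allowed deviation from the running baseline
#'   (m/s^2); `NULL` (default) uses 3x the MAD-based robust deviation of the
#'   trace, which passes compression pulses but clips hammering spikes.
#' @param median_window Odd window length (samples) of the median filter;
#'   default 5 (25 ms at 5 ms sampling), small enough to keep pulse peaks.
#' @param baseline_window_s Length (seconds) of the running-median window used
#'   as the amplitude-control baseline.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(lowpass_cutoff_hz = 15, amplitude_clamp = NULL,
                          median_window = 5, baseline_window_s = 1.5) {
  stopifnot(lowpass_cutoff_hz > 0)
  if (median_window %% 2 != 1 || median_window < 3)
    stop("median_window must be odd and >= 3")
  if (!is.null(amplitude_clamp) && amplitude_clamp <= 0)
    stop("amplitude_clamp must be > 0")
  stopifnot(baseline_window_s > 0)
  structure(list(lowpass_cutoff_hz = lowpass_cutoff_hz,
                 amplitude_clamp = amplitude_clamp,
                 median_window = as.integer(median_window),
                 baseline_window_s = baseline_window_s),
            class = "filter_config")
}

default_filter_config <- function() filter_config()

# sliding median with replicate padding; odd k
sliding_median <- function(x, k) {
  if (k == 1) return(x)
  h <- (k - 1L) %/% 2L
  padded <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(runmed(padded, k, endrule = "keep"))[(h + 1L):(h + length(x))]
}

#' Low-pass amplitude-controlled filter
#'
#' First clips samples whose deviation from a running-median baseline exceeds
#' the clamp (replacing them with the clamp boundary, sign preserved) to
#' suppress hammering anomalies, then applies a first-order low-pass
#' recursion to attenuate white noise.
#'
#' @param trace An [accel_trace()].
#' @param config A [filter_config()].
#' @return An [accel_trace()] of identical length and sampling interval
#'   (annotations carried through).
#' @export
lowpass_amplitude_filter <- function(trace, config = filter_config()) {
  stopifnot(inherits(trace, "accel_trace"), inherits(config, "filter_config"))
  x <- trace$samples
  dt <- trace$sampling_interval
  nyquist <- 1 / (2 * dt)
  if (config$lowpass_cutoff_hz >= nyquist)
    stop(sprintf("cutoff %.3g Hz must be below the Nyquist frequency %.3g Hz",
                 config$lowpass_cutoff_hz, nyquist))
  # amplitude control: clip excursions beyond the clamp from a slow baseline
  k <- round(config$baseline_window_s / dt)
  k <- max(3L, if (k %% 2 == 0) k + 1L else k)
  k <- min(k, if (length(x) %% 2 == 0) length(x) - 1L else length(x))
  baseline <- sliding_median(x, k)
  clamp <- config$amplitude_clamp
  if (is.null(clamp)) {
    clamp <- 3 * mad(x)
    if (clamp == 0) clamp <- Inf  # constant trace: nothing to clip
  }
  dev <- x - baseline
  x <- baseline + pmax(pmin(dev, clamp), -clamp)
  # first-order low-pass recursion y[i] = y[i-1] + a (x[i] - y[i-1]),
  # run forward then backward (zero phase) so pulse boundaries are not
  # delayed by the filter's group lag
  rc <- 1 / (2 * pi * config$lowpass_cutoff_hz)
  a <- dt / (rc + dt)
  y <- rev(single_pole_lowpass(rev(single_pole_lowpass(x, a)), a))
  accel_trace(y, dt, trace$annotations)
}

single_pole_lowpass <- function(x, a) {
  # y[i] = (1-a) y[i-1] + a x[i]; recursion via stats::filter for speed
  y <- stats::filter(a * x, 1 - a, method = "recursive", init = x[1])
  as.numeric(y)
}

#' Sliding-window median filter
#'
#' Each output sample is the median of the replicate-padded window centered
#' on it.
#'
#' @param trace An [accel_trace()].
#' @param window Odd window length in samples, at most the trace length.
#' @return An [accel_trace()] of identical length and sampling interval.
#' @export
median_filter <- function(trace, window = 5) {
  stopifnot(inherits(trace, "accel_trace"))
  if (window %% 2 != 1) stop("median filter window must be odd")
  if (window > length(trace$samples))
    stop("median filter window exceeds trace length")
  accel_trace(sliding_median(trace$samples, as.integer(window)),
              trace$sampling_interval, trace$annotations)
}

#' Apply the full filter chain
#'
#' Low-pass amplitude-controlled filtering followed by median filtering, the
#' order used throughout the pipeline.
#'
#' @inheritParams lowpass_amplitude_filter
#' @return The filtered [accel_trace()].
#' @export
apply_filters <- function(trace, config = filter_config()) {
  median_filter(lowpass_amplitude_filter(trace, config),
                config$median_window)
}
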