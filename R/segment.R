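#' Segmentation configuration
#'
#' Settings for the dual-sliding-window pulse recognizer and the max-value
#' alignment of cut pulses.
#'
#' @param alpha_percent Detection threshold as a percentage change from the
#'   static gravity value; a pulse candidate opens when the filtered signal
#'   deviates from baseline by more than `alpha_percent`% of it. Default 25,
#'   inside the empirical 21--32 range.
#' @param min_duration_s,max_duration_s Pulse-width restriction in seconds
#'   (defaults 0.25 / 0.60, from 100--120 compressions per minute).
#' @param min_amplitude Pulse-height restriction: minimum peak deviation from
#'   baseline (m/s^2) for a candidate to be kept.
#' @param effective_points Normalized pulse length L (samples kept per
#'   pulse); default 70.
#' @param window_len Sliding-window length in samples, bounding the backward
#'   search for the cut start.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(alpha_percent = 25, min_duration_s = 0.25,
                                max_duration_s = 0.60, min_amplitude = 3,
                                effective_points = 70, window_len = 60) {
  stopifnot(alpha_percent > 0, alpha_percent < 100,
            min_duration_s < max_duration_s, effective_points >= 2,
            min_amplitude >= 0, window_len >= 1)
  structure(list(alpha_percent = alpha_percent,
                 min_duration_s = min_duration_s,
                 max_duration_s = max_duration_s,
                 min_amplitude = min_amplitude,
                 effective_points = as.integer(effective_points),
                 window_len = as.integer(window_len)),
            class = "segmentation_config")
}

default_segmentation_config <- function() segmentation_config()

#' Estimate the static gravity value of a trace
#'
#' The quiescent accelerometer reading (the gravity projection) serves as the
#' detection baseline. It is estimated as the median of the quiescent
#' portions of the signal, located via the mode of a kernel density estimate:
#' baseline samples concentrate in a narrow band while compression samples
#' spread over the pulse amplitude.
#'
#' @param trace An [accel_trace()] (at least ~1 s of data recommended).
#' @return The estimated baseline (m/s^2).
#' @export
estimate_static_gravity <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  x <- trace$samples
  if (length(x) == 0) stop("empty trace")
  s <- mad(x)
  if (s == 0) return(median(x))
  d <- density(x, n = 512)
  mode_x <- d$x[which.max(d$y)]
  near <- x[abs(x - mode_x) <= max(3 * mad(x[abs(x - mode_x) <= s]), 1e-8)]
  if (length(near) == 0) return(mode_x)
  median(near)
}

#' One cut compression pulse
#'
#' @param samples The cut sub-sequence of the source trace.
#' @param start,end 1-based inclusive indices into the source trace.
#' @param peak Index (into the source trace) of the extreme deviation.
#' @return An object of class `pulse_segment`.
#' @export
pulse_segment <- function(samples, start, end, peak) {
  stopifnot(end - start + 1 >= 2, peak >= start, peak <= end,
            length(samples) == end - start + 1)
  structure(list(samples = as.numeric(samples), start = as.integer(start),
                 end = as.integer(end), peak = as.integer(peak)),
            class = "pulse_segment")
}

#' @export
print.pulse_segment <- function(x, ...) {
  cat(sprintf("<pulse_segment> [%d, %d] peak %d (%d samples)\n",
              x$start, x$end, x$peak, length(x$samples)))
  invisible(x)
}

# walk from index i towards lower indices while |dev| strictly decreases,
# bounded by `limit` steps; returns the index of the local minimum of |dev|
walk_to_local_min <- function(adev, i, step, limit) {
  taken <- 0L
  while (taken < limit) {
    j <- i + step
    if (j < 1L || j > length(adev)) break
    if (adev[j] >= adev[i]) break
    i <- j
    taken <- taken + 1L
  }
  i
}

#' Detect compression pulses with dual sliding windows
#'
#' Maintains a raw-sample window (A) and a filtered-sample window (B). A
#' candidate opens when the filtered deviation from the static gravity value
#' first exceeds `alpha_percent`% of it; the cut start is the optimal point
#' preceding the crossing — the last near-baseline sample refined to the
#' local minimum of deviation, taken from window B, or from window A when B
#' is flat there — and the cut ends where the signal returns to near
#' baseline. Candidates must pass three restrictions: duration within bounds,
#' peak deviation at least `min_amplitude`, and unimodality (exactly one
#' dominant extreme after filtering).
#'
#' @param raw,filtered The raw trace and its filter-chain output; equal
#'   length and sampling interval.
#' @param config A [segmentation_config()].
#' @return List of [pulse_segment()]s, disjoint and ordered; samples are cut
#'   from the raw trace.
#' @export
detect_pulses <- function(raw, filtered, config = segmentation_config()) {
  stopifnot(inherits(raw, "accel_trace"), inherits(filtered, "accel_trace"),
            inherits(config, "segmentation_config"))
  if (length(raw$samples) != length(filtered$samples))
    stop("raw and filtered traces must have equal length")
  dt <- raw$sampling_interval
  n <- length(raw$samples)
  g <- estimate_static_gravity(filtered)
  thr <- config$alpha_percent / 100 * abs(g)
  if (thr == 0) {  # zero-gravity mount: fall back to a robust signal scale
    thr <- config$alpha_percent / 100 * 6 * mad(filtered$samples)
    if (thr == 0) return(list())
  }
  devB <- abs(filtered$samples - g)   # window B: filtered
  devA <- abs(raw$samples - g)        # window A: raw
  min_len <- max(2L, round(config$min_duration_s / dt))
  max_len <- round(config$max_duration_s / dt)
  out <- list()
  i <- 1L
  last_end <- 0L
  while (i <= n) {
    if (devB[i] > thr) {
      # optimal start point: last sample within thr/2 of baseline before the
      # crossing, refined to the local minimum of deviation (window B; fall
      # back to window A when B carries no sub-threshold sample there)
      lo <- max(1L, i - config$window_len)
      below <- which(devB[lo:(i - 1L)] <= thr / 2)
      if (i == 1L) {
        start <- 1L
      } else if (length(below)) {
        start <- walk_to_local_min(devB, lo + below[length(below)] - 1L,
                                   -1L, config$window_len)
      } else {
        belowA <- which(devA[lo:(i - 1L)] <= thr / 2)
        start <- if (length(belowA)) lo + belowA[length(belowA)] - 1L else lo
      }
      start <- max(start, last_end + 1L)   # keep segments disjoint
      # advance to the pulse end: first return within thr/2 of baseline,
      # refined to the local minimum of deviation
      j <- i
      while (j < n && devB[j + 1L] > thr / 2) j <- j + 1L
      end <- walk_to_local_min(devB, min(j + 1L, n), 1L, config$window_len)
      seg_dev <- devB[start:end]
      keep <- {
        len <- end - start + 1L
        len >= min_len && len <= max_len &&          # (i) duration
          max(seg_dev) >= config$min_amplitude &&    # (ii) amplitude
          n_dominant_extremes(seg_dev) == 1L         # (iii) unimodality
      }
      if (keep) {
        # the cut waveform is taken from window B (the filtered signal)
        peak_rel <- which.max(seg_dev)
        out[[length(out) + 1]] <- pulse_segment(filtered$samples[start:end],
                                                start, end,
                                                start + peak_rel - 1L)
        last_end <- end
      }
      i <- end + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# count dominant extremes of the deviation: local maxima above half the peak,
# with neighbouring maxima merged unless the valley between them drops below
# 80% of the lower one (residual noise ripple on a broad pulse top must not
# split a single compression into two extremes)
n_dominant_extremes <- function(adev) {
  m <- length(adev)
  if (m < 3) return(1L)
  interior <- 2:(m - 1)
  is_max <- adev[interior] > adev[interior - 1] &
    adev[interior] >= adev[interior + 1]
  peaks <- interior[is_max & adev[interior] >= 0.5 * max(adev)]
  if (length(peaks) <= 1) return(length(peaks))
  count <- 1L
  for (i in 2:length(peaks)) {
    valley <- min(adev[peaks[i - 1]:peaks[i]])
    if (valley < 0.8 * min(adev[peaks[i - 1]], adev[peaks[i]]))
      count <- count + 1L
  }
  count
}

#' Normalize a cut pulse by max-value alignment with zero filling
#'
#' Subtracts the baseline, places the sample of maximum absolute deviation
#' (first occurrence on ties) at position `floor(0.75 L)` of a length-`L`
#' vector — 75% of the points to its left, 25% to its right — copies the
#' segment around it, zero-fills uncovered positions and truncates samples
#' falling outside the window.
#'
#' @param segment A [pulse_segment()].
#' @param L Normalized length (>= 2).
#' @param baseline Baseline to subtract before placement; default is the mean
#'   of the segment's first and last samples (both near-quiescent by
#'   construction of the cut).
#' @param label,depth_mm Optional label / true depth carried through.
#' @return A `normalized_pulse`: list with `values` (length `L`), `label`,
#'   `depth_mm`.
#' @export
align_and_pad <- function(segment, L, baseline = NULL, label = NULL,
                          depth_mm = NULL) {
  stopifnot(inherits(segment, "pulse_segment"))
  if (L < 2) stop("normalized length L must be >= 2")
  L <- as.integer(L)
  x <- segment$samples
  if (is.null(baseline)) baseline <- (x[1] + x[length(x)]) / 2
  x <- x - baseline
  p <- which.max(abs(x))                 # first occurrence on ties
  center <- floor(0.75 * L) + 1L         # 1-based position of the maximum
  values <- numeric(L)
  target <- center + seq_along(x) - p
  inside <- target >= 1L & target <= L
  values[target[inside]] <- x[inside]
  structure(list(values = values, label = label, depth_mm = depth_mm),
            class = "normalized_pulse")
}

#' @export
print.normalized_pulse <- function(x, ...) {
  cat(sprintf("<normalized_pulse> L=%d, max at %d", length(x$values),
              which.max(abs(x$values))))
  if (!is.null(x$label)) cat(sprintf(", label %d", x$label))
  cat("\n")
  invisible(x)
}

#' Filter, detect and normalize every pulse in a trace
#'
#' @param raw An [accel_trace()].
#' @param filter_config A [filter_config()].
#' @param segmentation_config A [segmentation_config()].
#' @return A [pulse_set()] with one row per detected pulse (labels and depths
#'   attached when the trace carries annotations).
#' @export
segment_trace <- function(raw, filter_config = NULL,
                          segmentation_config = NULL) {
  if (is.null(filter_config)) filter_config <- default_filter_config()
  if (is.null(segmentation_config))
    segmentation_config <- default_segmentation_config()
  filtered <- apply_filters(raw, filter_config)
  segs <- detect_pulses(raw, filtered, segmentation_config)
  L <- segmentation_config$effective_points
  if (length(segs) == 0)
    return(pulse_set(matrix(numeric(0), 0, L)))
  g <- estimate_static_gravity(filtered)
  vals <- t(vapply(segs, function(s)
    align_and_pad(s, L, baseline = g)$values, numeric(L)))
  labels <- NULL; depths <- NULL
  if (!is.null(raw$annotations)) {
    m <- match_segments(segs, raw$annotations)
    labels <- ifelse(is.na(m), NA_integer_, raw$annotations$label[m])
    depths <- ifelse(is.na(m), NA_real_, raw$annotations$depth_mm[m])
    if (anyNA(labels)) labels <- NULL    # unmatched pulses: leave unlabeled
    if (!is.null(labels)) depths <- depths else depths <- NULL
  }
  pulse_set(vals, labels, depths)
}
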