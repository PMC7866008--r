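#' Simulator configuration
#'
#' Parameters controlling the synthetic chest-compression accelerometry
#' generator. Defaults emulate manikin CPR recorded by a chest-mounted
#' accelerometer: compressions at 100--120 per minute sampled every 5 ms, a
#' static-gravity baseline, white sensor noise, and occasional "hammering"
#' spike anomalies. Compression depth is drawn from a three-component mixture
#' covering insufficient (< 50 mm), correct (50--60 mm) and excessive
#' (> 60 mm) depths.
#'
#' @param sampling_interval Sampling interval in seconds (default 0.005,
#'   i.e. one sample every 5 ms).
#' @param rate_per_minute Length-2 numeric range of compressions per minute;
#'   each compression draws its instantaneous rate uniformly from this range.
#' @param depth_weights Mixture weights for (insufficient, correct, excessive)
#'   depth classes; need not sum to 1.
#' @param depth_ranges List with numeric ranges (mm) `insufficient`,
#'   `correct`, `excessive` from which depths are drawn uniformly.
#' @param amplitude_per_mm Peak acceleration added per mm of depth
#'   (m/s^2 per mm); the amplitude map is linear in depth.
#' @param gravity_baseline Quiescent accelerometer reading (m/s^2).
#' @param noise_sd Standard deviation of additive white noise (m/s^2).
#' @param spike_rate Expected spike anomalies per minute.
#' @param spike_magnitude Length-2 range of spike heights (m/s^2).
#' @param inter_pulse_gap Length-2 range (seconds) of the quiescent gap
#'   between the end of one compression and the start of the next.
#' @param drift_rw_sd Per-sample standard deviation of an optional random-walk
#'   baseline drift (m/s^2); 0 disables drift.
#' @param seed Integer seed; all randomness flows from it.
#'
#' @return An object of class `simulator_config`.
#' @export
simulator_config <- function(sampling_interval = 0.005,
                             rate_per_minute = c(100, 120),
                             depth_weights = c(0.25, 0.5, 0.25),
                             depth_ranges = list(insufficient = c(35, 50),
                                                 correct = c(50, 60),
                                                 excessive = c(60, 75)),
                             amplitude_per_mm = 0.2,
                             gravity_baseline = 9.8,
                             noise_sd = 0.3,
                             spike_rate = 4,
                             spike_magnitude = c(10, 20),
                             inter_pulse_gap = c(0.08, 0.18),
                             drift_rw_sd = 0,
                             seed = 1L) {
  stopifnot(is.numeric(sampling_interval), length(sampling_interval) == 1,
            sampling_interval > 0)
  rate_per_minute <- sort(as.numeric(rate_per_minute))
  if (length(rate_per_minute) != 2 ||
      rate_per_minute[1] <= 0 || rate_per_minute[2] >= 300)
    stop("rate_per_minute must be a range within (0, 300)")
  if (length(depth_weights) != 3 || any(depth_weights < 0) ||
      sum(depth_weights) <= 0)
    stop("depth_weights must be 3 non-negative weights")
  for (r in depth_ranges)
    if (any(r <= 0)) stop("depth ranges must be positive (mm)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (amplitude_per_mm <= 0) stop("amplitude_per_mm must be > 0")
  structure(list(sampling_interval = sampling_interval,
                 rate_per_minute = rate_per_minute,
                 depth_weights = depth_weights / sum(depth_weights),
                 depth_ranges = depth_ranges,
                 amplitude_per_mm = amplitude_per_mm,
                 gravity_baseline = gravity_baseline,
                 noise_sd = noise_sd,
                 spike_rate = spike_rate,
                 spike_magnitude = as.numeric(spike_magnitude),
                 inter_pulse_gap = as.numeric(inter_pulse_gap),
                 drift_rw_sd = drift_rw_sd,
                 seed = as.integer(seed)),
            class = "simulator_config")
}

#' Accelerometer trace constructor
#'
#' @param samples Numeric vector of acceleration values (m/s^2).
#' @param sampling_interval Sampling interval in seconds.
#' @param annotations Optional data frame of per-pulse ground truth with
#'   columns `start`, `end`, `peak` (1-based sample indices, `start`/`end`
#'   inclusive), `depth_mm` and `label`.
#'
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(samples, sampling_interval, annotations = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1) stop("trace must contain at least one sample")
  if (!all(is.finite(samples))) stop("trace samples must be finite")
  stopifnot(sampling_interval > 0)
  if (!is.null(annotations)) {
    stopifnot(all(c("start", "end", "peak", "depth_mm", "label") %in%
                    names(annotations)))
    if (nrow(annotations) > 1) {
      if (is.unsorted(annotations$start, strictly = TRUE))
        stop("annotations must be sorted by start index")
      if (any(annotations$start[-1] <= annotations$end[-nrow(annotations)]))
        stop("annotations must not overlap")
    }
    if (any(annotations$start >= annotations$peak |
            annotations$peak >= annotations$end))
      stop("annotation indices must satisfy start < peak < end")
  }
  structure(list(samples = samples,
                 sampling_interval = sampling_interval,
                 annotations = annotations),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  dur <- length(x$samples) * x$sampling_interval
  cat(sprintf("<accel_trace> %d samples @ %.4g s (%.1f s)", length(x$samples),
              x$sampling_interval, dur))
  if (!is.null(x$annotations))
    cat(sprintf(", %d annotated pulses", nrow(x$annotations)))
  cat("\n")
  invisible(x)
}

#' @export
length.accel_trace <- function(x) length(x$samples)

#' Raised-cosine compression pulse template
#'
#' One compression is modelled as a smooth unimodal deflection from the
#' quiescent baseline: a raised cosine that starts and ends at zero and peaks
#' at `amplitude` mid-pulse. Real compression waveforms are not published in
#' analytic form; this template matches their filtered appearance
#' (smooth, single-lobed) and makes amplitude a clean proxy for depth.
#'
#' @param n Number of samples (>= 3).
#' @param amplitude Peak deflection (m/s^2).
#' @return Numeric vector of length `n` with `template[1] == template[n] == 0`.
#' @export
pulse_template <- function(n, amplitude) {
  stopifnot(n >= 3)
  amplitude * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))) / 2
}

#' Label a compression depth as correct or abnormal
#'
#' A compression is correct (label 1) when its depth lies in the recommended
#' 5--6 cm band, boundaries included; shallower or deeper compressions are
#' abnormal (label 0).
#'
#' @param depth_mm Compression depth in millimetres (> 0); vectorized.
#' @return Integer vector of 0/1 labels.
#' @export
depth_to_label <- function(depth_mm) {
  if (any(!is.finite(depth_mm)) || any(depth_mm <= 0))
    stop("depth_mm must be positive and finite")
  as.integer(depth_mm >= 50 & depth_mm <= 60)
}

# Draw the pulse schedule (rates, gaps, durations, depths) for one trace.
# Schedule randomness is consumed before any noise so that the same seed with
# and without noise yields identical pulse placement.
draw_schedule <- function(config, duration) {
  dt <- config$sampling_interval
  gap0 <- runif(1, config$inter_pulse_gap[1], config$inter_pulse_gap[2])
  t_cur <- gap0
  rows <- list()
  repeat {
    rate <- runif(1, config$rate_per_minute[1], config$rate_per_minute[2])
    period <- 60 / rate
    gap <- runif(1, config$inter_pulse_gap[1], config$inter_pulse_gap[2])
    pulse_dur <- period - gap
    if (t_cur + pulse_dur > duration) break
    cls <- sample.int(3, 1, prob = config$depth_weights)
    rng <- config$depth_ranges[[cls]]
    depth <- runif(1, rng[1], rng[2])
    rows[[length(rows) + 1]] <- c(t_start = t_cur, dur = pulse_dur,
                                  depth = depth)
    t_cur <- t_cur + period
  }
  if (length(rows) == 0) return(NULL)
  as.data.frame(do.call(rbind, rows))
}

#' Simulate a chest-compression accelerometer trace
#'
#' Builds a noise-free train of raised-cosine compression pulses on the
#' static-gravity baseline, annotates the ground truth (pre-noise), then
#' superimposes white noise, optional random-walk drift, and spike anomalies.
#'
#' @param config A [simulator_config()].
#' @param duration Trace duration in seconds; must cover at least one
#'   compression period.
#' @return An [accel_trace()] of `round(duration / sampling_interval)` samples
#'   with ground-truth `annotations`.
#' @export
simulate_trace <- function(config, duration) {
  stopifnot(inherits(config, "simulator_config"))
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("duration must be a positive number of seconds")
  if (duration < 60 / config$rate_per_minute[1])
    stop("duration must cover at least one compression period")
  dt <- config$sampling_interval
  n <- round(duration / dt)
  set.seed(config$seed)
  sched <- draw_schedule(config, duration)
  x <- rep(config$gravity_baseline, n)
  ann <- NULL
  if (!is.null(sched)) {
    ann_rows <- vector("list", nrow(sched))
    for (i in seq_len(nrow(sched))) {
      start <- round(sched$t_start[i] / dt) + 1L
      m <- round(sched$dur[i] / dt)
      if (m < 3 || start + m - 1L > n) next
      amp <- config$amplitude_per_mm * sched$depth[i]
      tmpl <- pulse_template(m, amp)
      idx <- start:(start + m - 1L)
      x[idx] <- x[idx] + tmpl
      peak <- start + which.max(tmpl) - 1L
      ann_rows[[i]] <- data.frame(start = start, end = start + m - 1L,
                                  peak = peak, depth_mm = sched$depth[i],
                                  label = depth_to_label(sched$depth[i]))
    }
    ann_rows <- ann_rows[!vapply(ann_rows, is.null, logical(1))]
    if (length(ann_rows)) ann <- do.call(rbind, ann_rows)
  }
  if (config$noise_sd > 0) x <- x + rnorm(n, 0, config$noise_sd)
  if (config$drift_rw_sd > 0) x <- x + cumsum(rnorm(n, 0, config$drift_rw_sd))
  if (config$spike_rate > 0) {
    n_spikes <- rpois(1, config$spike_rate * duration / 60)
    if (n_spikes > 0) {
      pos <- sample.int(n, n_spikes)
      mag <- runif(n_spikes, config$spike_magnitude[1],
                   config$spike_magnitude[2])
      x[pos] <- x[pos] + mag
    }
  }
  accel_trace(x, dt, ann)
}

#' Build a labelled dataset of normalized compression pulses
#'
#' Repeatedly simulates traces and runs them through the full filtering and
#' segmentation path, matching each detected pulse back to its ground-truth
#' annotation for the depth label, until `n` pulses with the requested class
#' balance are collected.
#'
#' @param n Number of pulses (>= 1).
#' @param correct_fraction Requested fraction of correct-depth pulses
#'   (label 1); achieved within 1/n.
#' @param config A [simulator_config()]; its `seed` makes the dataset
#'   reproducible.
#' @param filter_config,segmentation_config Configs for the preprocessing and
#'   segmentation stages (defaults used when `NULL`).
#' @param trace_duration Duration (s) of each simulated trace.
#' @param max_traces Attempt bound; generation fails if the class quotas are
#'   not met after this many traces.
#' @return A [pulse_set()] of `n` normalized pulses with labels and depths.
#' @export
make_dataset <- function(n, correct_fraction = 0.5, config = simulator_config(),
                         filter_config = NULL, segmentation_config = NULL,
                         trace_duration = 60, max_traces = 200) {
  stopifnot(n >= 1, correct_fraction >= 0, correct_fraction <= 1)
  if (is.null(filter_config)) filter_config <- default_filter_config()
  if (is.null(segmentation_config))
    segmentation_config <- default_segmentation_config()
  n1 <- round(n * correct_fraction)
  n0 <- n - n1
  pool1 <- list(); pool0 <- list()
  d1 <- numeric(); d0 <- numeric()
  tr <- 0L
  while ((length(pool1) < n1 || length(pool0) < n0) && tr < max_traces) {
    tr <- tr + 1L
    cfg_i <- config
    cfg_i$seed <- config$seed + tr
    trace <- simulate_trace(cfg_i, trace_duration)
    if (is.null(trace$annotations)) next
    filtered <- apply_filters(trace, filter_config)
    segs <- detect_pulses(trace, filtered, segmentation_config)
    if (length(segs) == 0) next
    g <- estimate_static_gravity(filtered)
    matched <- match_segments(segs, trace$annotations)
    for (k in seq_along(segs)) {
      j <- matched[k]
      if (is.na(j)) next
      np <- align_and_pad(segs[[k]], segmentation_config$effective_points,
                          baseline = g)
      lab <- trace$annotations$label[j]
      dep <- trace$annotations$depth_mm[j]
      if (lab == 1L && length(pool1) < n1) {
        pool1[[length(pool1) + 1]] <- np$values; d1 <- c(d1, dep)
      } else if (lab == 0L && length(pool0) < n0) {
        pool0[[length(pool0) + 1]] <- np$values; d0 <- c(d0, dep)
      }
    }
  }
  if (length(pool1) < n1 || length(pool0) < n0)
    stop(sprintf(paste0("could not reach class balance after %d traces ",
                        "(have %d correct / %d abnormal, need %d / %d)"),
                 tr, length(pool1), length(pool0), n1, n0))
  vals <- do.call(rbind, c(pool1, pool0))
  labels <- c(rep(1L, n1), rep(0L, n0))
  depths <- c(d1, d0)
  # deterministic interleave so classes are not block-ordered
  set.seed(config$seed)
  ord <- sample.int(n)
  pulse_set(vals[ord, , drop = FALSE], labels[ord], depths[ord])
}

# Match each segment to the annotation it overlaps most; NA when the best
# overlap covers less than half the annotation.
match_segments <- function(segments, annotations) {
  vapply(segments, function(s) {
    ov <- pmin(s$end, annotations$end) - pmax(s$start, annotations$start) + 1
    ov <- pmax(ov, 0)
    j <- which.max(ov)
    need <- 0.5 * (annotations$end[j] - annotations$start[j] + 1)
    if (ov[j] >= need) j else NA_integer_
  }, integer(1))
}

#' Container for fixed-length normalized pulses
#'
#' @param values Numeric matrix, one pulse per row.
#' @param label Optional integer vector of 0/1 labels (one per row).
#' @param depth_mm Optional numeric vector of true depths (mm).
#' @return An object of class `pulse_set`.
#' @export
pulse_set <- function(values, label = NULL, depth_mm = NULL) {
  values <- as.matrix(values)
  if (!is.null(label)) {
    stopifnot(length(label) == nrow(values), all(label %in% c(0L, 1L)))
    label <- as.integer(label)
  }
  if (!is.null(depth_mm)) stopifnot(length(depth_mm) == nrow(values))
  structure(list(values = values, label = label, depth_mm = depth_mm),
            class = "pulse_set")
}

#' @export
print.pulse_set <- function(x, ...) {
  cat(sprintf("<pulse_set> %d pulses x %d points", nrow(x$values),
              ncol(x$values)))
  if (!is.null(x$label))
    cat(sprintf(" (%d correct / %d abnormal)", sum(x$label == 1L),
                sum(x$label == 0L)))
  cat("\n")
  invisible(x)
}

#' @export
length.pulse_set <- function(x) nrow(x$values)
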