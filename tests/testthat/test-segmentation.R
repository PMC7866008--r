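test_that("static gravity estimation is robust", {
  expect_equal(estimate_static_gravity(accel_trace(rep(2.5, 300), 0.005)), 2.5)
  set.seed(6)
  tr <- accel_trace(9.8 + rnorm(2000, 0, 0.1), 0.005)
  expect_lt(abs(estimate_static_gravity(tr) - 9.8), 0.05)
  # baseline plus sparse pulses (< 20% duty cycle)
  x <- rep(9.8, 4000)
  for (s in seq(200, 3800, 400)) x[s:(s + 60)] <- x[s:(s + 60)] +
      pulse_template(61, 8)
  expect_lt(abs(estimate_static_gravity(accel_trace(x, 0.005)) - 9.8),
            0.02 * 9.8)
  expect_error(estimate_static_gravity(accel_trace(numeric(0), 0.005)))
})

test_that("noise-free pulses are recovered with >= 90% annotation overlap", {
  cfg <- simulator_config(noise_sd = 0, spike_rate = 0, seed = 11)
  tr <- simulate_trace(cfg, 4)
  ann <- tr$annotations
  expect_gte(nrow(ann), 5)
  filtered <- apply_filters(tr)
  segs <- detect_pulses(tr, filtered)
  expect_equal(length(segs), nrow(ann))
  for (i in seq_along(segs)) {
    ov <- min(segs[[i]]$end, ann$end[i]) - max(segs[[i]]$start, ann$start[i]) + 1
    expect_gte(ov / (ann$end[i] - ann$start[i] + 1), 0.9)
  }
})

test_that("flat traces and sub-duration blips yield no pulses", {
  flat <- accel_trace(rep(9.8, 2000), 0.005)
  expect_length(detect_pulses(flat, apply_filters(flat)), 0)
  # one 50 ms blip: crosses the threshold but fails the duration restriction
  x <- rep(9.8, 2000)
  x[1000:1009] <- 9.8 + pulse_template(10, 8)
  blip <- accel_trace(x, 0.005)
  expect_length(detect_pulses(blip, apply_filters(blip)), 0)
})

test_that("detected segments are disjoint, ordered, and length-checked", {
  tr <- simulate_trace(simulator_config(seed = 13), 30)
  filtered <- apply_filters(tr)
  segs <- detect_pulses(tr, filtered)
  expect_gt(length(segs), 10)
  starts <- vapply(segs, `[[`, integer(1), "start")
  ends <- vapply(segs, `[[`, integer(1), "end")
  expect_true(all(diff(starts) > 0))
  expect_true(all(starts[-1] > ends[-length(ends)]))
  expect_error(detect_pulses(tr, accel_trace(rep(1, 10), 0.005)),
               "equal length")
})

test_that("detection is invariant to a constant offset of the whole trace", {
  # exact cut boundaries noise-free (the baseline is re-estimated, and the
  # local-minimum refinement pins the boundaries)
  tr0 <- simulate_trace(simulator_config(seed = 14, noise_sd = 0,
                                         spike_rate = 0), 20)
  sh0 <- accel_trace(tr0$samples + 4.2, tr0$sampling_interval,
                     tr0$annotations)
  s1 <- detect_pulses(tr0, apply_filters(tr0))
  s2 <- detect_pulses(sh0, apply_filters(sh0))
  expect_equal(vapply(s1, `[[`, integer(1), "start"),
               vapply(s2, `[[`, integer(1), "start"))
  expect_equal(vapply(s1, `[[`, integer(1), "end"),
               vapply(s2, `[[`, integer(1), "end"))
  # same pulses recovered under noise
  tr <- simulate_trace(simulator_config(seed = 14), 20)
  sh <- accel_trace(tr$samples - 3.1, tr$sampling_interval, tr$annotations)
  expect_equal(segmentation_scores(sh), segmentation_scores(tr))
})

test_that("max-value alignment places the peak at floor(0.75 L)", {
  seg <- pulse_segment(c(0, 1, 3, 1, 0), 101, 105, 103)
  np <- align_and_pad(seg, 8, baseline = 0)
  expect_equal(np$values, c(0, 0, 0, 0, 0, 1, 3, 1))
  # single-sample placement
  seg1 <- pulse_segment(c(0, 7), 10, 11, 11)
  np1 <- align_and_pad(seg1, 10, baseline = 0)
  expect_equal(np1$values[floor(0.75 * 10) + 1], 7)
  expect_equal(sum(np1$values != 0), 1)
  # long left tail is truncated, max stays in place
  long <- pulse_segment(c(rep(0.5, 80), 3, 0.5), 1, 82, 81)
  npl <- align_and_pad(long, 20, baseline = 0)
  expect_equal(which.max(abs(npl$values)), floor(0.75 * 20) + 1)
  expect_length(npl$values, 20)
  expect_error(align_and_pad(seg, 1), "L")
})

test_that("alignment invariant holds over random segments", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(3:120, 1)
    L <- sample(8:90, 1)
    x <- rnorm(n)
    seg <- pulse_segment(x, 1, n, which.max(abs(x)))
    np <- align_and_pad(seg, L, baseline = 0)
    expect_length(np$values, L)
    center <- floor(0.75 * L) + 1
    expect_equal(np$values[center], x[which.max(abs(x))])
    expect_equal(which.max(abs(np$values)), center)
    # fill positions are exactly zero
    covered <- center + seq_len(n) - which.max(abs(x))
    covered <- covered[covered >= 1 & covered <= L]
    expect_true(all(np$values[setdiff(seq_len(L), covered)] == 0))
  }
})

test_that("segment_trace composes filter, detect and align deterministically", {
  tr <- simulate_trace(simulator_config(rate_per_minute = c(110, 110),
                                        seed = 15), 60)
  ps <- segment_trace(tr)
  expect_s3_class(ps, "pulse_set")
  expect_true(abs(length(ps) - 110) <= 3)
  expect_equal(ncol(ps$values), 70)
  ps2 <- segment_trace(tr)
  expect_identical(ps$values, ps2$values)
  # empty trace -> empty set
  flat <- accel_trace(rep(9.8, 3000), 0.005)
  expect_length(segment_trace(flat), 0)
})

test_that("segmentation recovers simulated pulses at high SNR", {
  scores <- vapply(1:50, function(s) {
    tr <- simulate_trace(simulator_config(seed = 100 + s), 20)
    segmentation_scores(tr)
  }, numeric(2))
  expect_gte(min(scores["recall", ]), 0.95)
  expect_gte(min(scores["precision", ]), 0.95)
})
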