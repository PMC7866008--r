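test_that("simulated traces have the requested length and sampling", {
  cfg <- simulator_config(rate_per_minute = c(110, 110), seed = 1)
  tr <- simulate_trace(cfg, 60)
  expect_s3_class(tr, "accel_trace")
  expect_equal(length(tr), 12000)  # 60 s / 5 ms
  expect_equal(tr$sampling_interval, 0.005)
  expect_true(all(is.finite(tr$samples)))
  expect_error(simulate_trace(cfg, -1), "duration")
})

test_that("simulation is deterministic given the seed", {
  cfg <- simulator_config(seed = 42)
  a <- simulate_trace(cfg, 20)
  b <- simulate_trace(cfg, 20)
  expect_identical(a$samples, b$samples)
  expect_identical(a$annotations, b$annotations)
})

test_that("noise-free pulse amplitude follows the linear depth map", {
  cfg <- simulator_config(noise_sd = 0, spike_rate = 0, seed = 5)
  tr <- simulate_trace(cfg, 10)
  ann <- tr$annotations
  for (i in seq_len(nrow(ann))) {
    seg <- tr$samples[ann$start[i]:ann$end[i]]
    amp <- cfg$amplitude_per_mm * ann$depth_mm[i]
    # exact against the sampled template; the nominal amplitude is only
    # attained exactly when a sample falls on the continuous peak
    expect_equal(max(abs(seg - cfg$gravity_baseline)),
                 max(pulse_template(length(seg), amp)))
    expect_equal(max(abs(seg - cfg$gravity_baseline)), amp,
                 tolerance = 1e-3)
  }
})

test_that("noise-free trace is exactly the sum of baseline and templates", {
  cfg <- simulator_config(noise_sd = 0, spike_rate = 0, seed = 9)
  tr <- simulate_trace(cfg, 30)
  recon <- rep(cfg$gravity_baseline, length(tr))
  ann <- tr$annotations
  for (i in seq_len(nrow(ann))) {
    idx <- ann$start[i]:ann$end[i]
    recon[idx] <- recon[idx] +
      pulse_template(length(idx), cfg$amplitude_per_mm * ann$depth_mm[i])
  }
  expect_equal(max(abs(tr$samples - recon)), 0)
})

test_that("pulse count and inter-peak interval match the configured rate", {
  cfg <- simulator_config(rate_per_minute = c(110, 110), noise_sd = 0,
                          spike_rate = 0, seed = 2)
  tr <- simulate_trace(cfg, 60)
  expect_true(abs(nrow(tr$annotations) - 110) <= 1)
  cfg2 <- simulator_config(seed = 3)  # default range [100, 120]
  tr2 <- simulate_trace(cfg2, 60)
  gaps <- diff(tr2$annotations$peak) * tr2$sampling_interval
  expect_gte(mean(gaps), 60 / 120)
  expect_lte(mean(gaps), 60 / 100)
})

test_that("depth labels mark the 5-6 cm band inclusively", {
  expect_identical(depth_to_label(55), 1L)
  expect_identical(depth_to_label(65), 0L)
  expect_identical(depth_to_label(50), 1L)
  expect_identical(depth_to_label(60), 1L)
  expect_identical(depth_to_label(49.999), 0L)
  expect_error(depth_to_label(0), "positive")
  expect_error(depth_to_label(-5), "positive")
})

test_that("annotation labels are consistent with depth_to_label", {
  set.seed(17)
  depths <- runif(1000, 30, 80)
  expect_identical(depth_to_label(depths),
                   as.integer(depths >= 50 & depths <= 60))
  tr <- simulate_trace(simulator_config(seed = 21), 60)
  ann <- tr$annotations
  expect_identical(ann$label, depth_to_label(ann$depth_mm))
})

test_that("make_dataset hits the requested size and class balance", {
  ds <- make_dataset(50, 0.4, simulator_config(seed = 8), trace_duration = 30)
  expect_s3_class(ds, "pulse_set")
  expect_equal(length(ds), 50)
  expect_equal(sum(ds$label == 1L), 20)
  expect_true(all(ncol(ds$values) == 70))
  ds2 <- make_dataset(50, 0.4, simulator_config(seed = 8),
                      trace_duration = 30)
  expect_identical(ds$label, ds2$label)
  expect_identical(ds$values, ds2$values)
})

test_that("unreachable class balance raises a generation error", {
  cfg <- simulator_config(seed = 1, depth_weights = c(1, 0, 0))
  expect_error(make_dataset(10, 0.5, cfg, trace_duration = 10,
                            max_traces = 2),
               "class balance")
})

test_that("simulator configuration is validated", {
  expect_error(simulator_config(sampling_interval = 0))
  expect_error(simulator_config(rate_per_minute = c(0, 100)))
  expect_error(simulator_config(noise_sd = -1), "noise_sd")
  expect_error(simulator_config(depth_ranges = list(a = c(-1, 5), b = c(50, 60),
                                                    c = c(60, 70))),
               "positive")
})
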