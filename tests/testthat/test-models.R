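test_that("named architectures match their printed structure", {
  lenet <- build_architecture("lenet5_1d")
  expect_equal(lenet$input_length, 70)
  expect_equal(ccdnet:::flatten_length(lenet), 64 * 17)  # 1088
  cp4 <- build_architecture("cpcnn4")
  expect_equal(ccdnet:::flatten_length(cp4), 128 * 9)    # 1152
  cp5 <- build_architecture("cpcnn5")
  expect_equal(vapply(cp5$conv_blocks, `[`, integer(1), 2), c(11, 7, 5, 3))
  expect_error(build_architecture("vgg"), "unknown")
  expect_error(architecture_spec("even", 70, list(c(8, 4)), 16), "odd")
})

test_that("closed-form parameter counts match materialized models", {
  # single conv 1 -> 1, kernel 3, with bias
  tiny <- architecture_spec("one", 8, list(c(1, 3)), integer(0))
  expect_equal(count_parameters(tiny, include_batch_norm = FALSE),
               4 + 2 * (1 * 4 + 1))  # conv + the 2-class output layer
  for (nm in c("lenet5_1d", "cpcnn4", "cpcnn5")) {
    for (bn in c(FALSE, TRUE)) {
      sp <- build_architecture(nm, batch_norm = bn)
      set.seed(1)
      expect_equal(count_parameters(sp), n_trainable(init_model(sp)))
    }
  }
  expect_equal(count_parameters(build_architecture("lenet5_1d"),
                                include_batch_norm = FALSE), 158274L)
  expect_equal(count_parameters(build_architecture("cpcnn4"),
                                include_batch_norm = FALSE), 191234L)
})

test_that("forward pass yields valid probabilities and the conv identity", {
  sp <- build_architecture("cpcnn4")
  set.seed(3)
  m <- init_model(sp)
  X <- matrix(rnorm(7 * 72), 7)
  p <- model_forward(m, X)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  expect_error(model_forward(m, matrix(0, 2, 70)), "input_length")
  # the elementary convolution sum on a hand-checked case
  expect_equal(conv1d(c(1, 2, 3), c(1, 1)), c(3, 5))
  expect_equal(conv1d(c(1, 2, 3), c(2, 0, 1), b = 1), 6)
  # all-zero weights give symmetric posteriors
  m0 <- m
  m0$params <- lapply(m0$params, function(x) x * 0)
  expect_equal(unname(model_forward(m0, X)[, 1]), rep(0.5, 7))
})

test_that("cross-entropy matches its defining arithmetic", {
  expect_equal(cross_entropy(0.5, 1), log(2))
  expect_lt(cross_entropy(1 - 1e-9, 1), 1e-6)
  a <- cross_entropy(0.3, 1)
  b <- cross_entropy(0.8, 0)
  expect_equal(cross_entropy(c(0.3, 0.8), c(1, 0)), (a + b) / 2)
  expect_warning(cross_entropy(c(0, 0.5), c(1, 1)), "clamped")
})

test_that("backpropagation matches finite-difference gradients", {
  sp <- architecture_spec("tiny", 12, list(c(3, 3), c(4, 3)), c(5),
                          batch_norm = TRUE, dropout_conv = 0,
                          dropout_fc = 0)
  set.seed(42)
  m <- init_model(sp)
  X <- matrix(rnorm(6 * 12), 6)
  y <- c(0, 1, 1, 0, 1, 0)
  fwd <- ccdnet:::nn_forward(m, X, training = TRUE, keep_cache = TRUE)
  gr <- ccdnet:::nn_backward(m, fwd, y)
  lossfun <- function(params) {
    m2 <- m
    m2$params <- params
    cross_entropy(ccdnet:::nn_forward(m2, X, training = TRUE)$probs, y)
  }
  eps <- 1e-6
  for (nm in names(gr)) {
    for (i in sample(length(m$params[[nm]]),
                     min(4, length(m$params[[nm]])))) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("feature maps are translation-covariant before flattening", {
  sp <- build_architecture("cpcnn4")
  set.seed(8)
  m <- init_model(sp)
  x <- numeric(72)
  x[30:40] <- pulse_template(11, 5)   # bump away from the edges
  x2 <- numeric(72)
  x2[32:42] <- pulse_template(11, 5)  # shifted by 2 samples
  f1 <- ccdnet:::nn_forward(m, matrix(x, 1), training = FALSE)$features[[1]]
  f2 <- ccdnet:::nn_forward(m, matrix(x2, 1), training = FALSE)$features[[1]]
  # shift by 2 inputs = 1 pooled position; compare away from the borders
  keep <- 8:30
  expect_equal(f1[1, keep, ], f2[1, keep + 1, ], tolerance = 1e-10)
})

test_that("training is reproducible and learns separable data", {
  ds <- make_dataset(80, 0.5, separable_simulator(2), trace_duration = 30,
                     segmentation_config = segmentation_config(
                       effective_points = 72))
  cfg <- train_config(iterations = 60, batch_size = 20, seed = 7)
  f1 <- train_model("cpcnn4", ds, config = cfg)
  f2 <- train_model("cpcnn4", ds, config = cfg)
  expect_identical(tail(f1$history$loss$loss, 1),
                   tail(f2$history$loss$loss, 1))
  # loss decreases over the first iterations (median across seeds)
  drops <- vapply(1:3, function(s) {
    f <- train_model("cpcnn4", ds,
                     config = train_config(iterations = 50, batch_size = 20,
                                           seed = s))
    h <- f$history$loss$loss
    mean(tail(h, 10)) < mean(head(h, 10))
  }, logical(1))
  expect_gte(sum(drops), 2)
  expect_error(train_model("cpcnn4",
                           pulse_set(ds$values, rep(1L, length(ds))),
                           config = cfg),
               "both classes")
})

test_that("wider first kernels learn no slower (soft regression guard)", {
  ds <- make_dataset(80, 0.5, separable_simulator(4), trace_duration = 30,
                     segmentation_config = segmentation_config(
                       effective_points = 72))
  iters_to <- function(first_k, seed) {
    sp <- architecture_spec(paste0("k", first_k), 72,
                            list(c(32, first_k), c(64, 5), c(128, 3)),
                            c(128, 64), batch_norm = TRUE)
    f <- train_model(sp, ds, config = train_config(iterations = 80,
                                                   batch_size = 20,
                                                   seed = seed))
    h <- f$history$loss$loss
    i <- which(h < 0.3)[1]
    if (is.na(i)) Inf else i
  }
  wide <- median(vapply(1:3, function(s) iters_to(11, s), numeric(1)))
  narrow <- median(vapply(1:3, function(s) iters_to(5, s), numeric(1)))
  if (wide > narrow)
    warning(sprintf(paste0("wide first kernel reached the loss threshold ",
                           "later than the narrow one (%.0f vs %.0f ",
                           "iterations)"), wide, narrow))
  succeed()
})
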