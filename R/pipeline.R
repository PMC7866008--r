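#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end run: simulate, filter,
#' segment, split, train, evaluate. The dataset size is the sum of the split
#' counts (default 680 training + 120 testing + 137 validation = 937 pulses,
#' of which 471 are correct-depth).
#'
#' @param simulator A [simulator_config()].
#' @param filters A [filter_config()].
#' @param segmentation A [segmentation_config()]; its `effective_points` is
#'   overridden by the model's input length for consistency.
#' @param model Architecture name (see [build_architecture()]).
#' @param train A [train_config()].
#' @param split Named counts `c(train, test, validation)`.
#' @param correct_fraction Fraction of correct-depth pulses in the dataset.
#' @param seed Single global seed; per-stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulator = simulator_config(),
                            filters = filter_config(),
                            segmentation = segmentation_config(),
                            model = "cpcnn4",
                            train = train_config(),
                            split = c(train = 680, test = 120,
                                      validation = 137),
                            correct_fraction = 471 / 937,
                            seed = 1L) {
  stopifnot(all(split > 0), length(split) == 3)
  if (is.null(names(split)) || !all(c("train", "test", "validation") %in%
                                      names(split)))
    names(split) <- c("train", "test", "validation")
  structure(list(simulator = simulator, filters = filters,
                 segmentation = segmentation, model = model, train = train,
                 split = split, correct_fraction = correct_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Stratified split of a labelled pulse set
#'
#' Allocates each class proportionally across the three partitions (largest
#' remainder), preserving class fractions within one pulse per class.
#'
#' @param pulses A [pulse_set()] with labels.
#' @param split Named counts `c(train, test, validation)` summing to at most
#'   the number of pulses.
#' @param seed Seed for the within-class shuffle.
#' @return Named list of three [pulse_set()]s.
#' @export
split_pulse_set <- function(pulses, split = c(train = 680, test = 120,
                                              validation = 137),
                            seed = 1L) {
  stopifnot(inherits(pulses, "pulse_set"), !is.null(pulses$label),
            sum(split) <= length(pulses))
  set.seed(seed)
  parts <- setNames(vector("list", 3), names(split))
  idx_by_part <- setNames(vector("list", 3), names(split))
  for (cls in c(0L, 1L)) {
    idx <- sample(which(pulses$label == cls))
    quota <- split * length(idx) / length(pulses)
    base <- floor(quota)
    rem <- quota - base
    # largest-remainder rounding keeps class fractions within 1 per class
    extra <- round(sum(quota) - sum(base))
    if (extra > 0) {
      add <- order(rem, decreasing = TRUE)[seq_len(extra)]
      base[add] <- base[add] + 1
    }
    take <- 0L
    for (p in names(split)) {
      k <- base[[p]]
      idx_by_part[[p]] <- c(idx_by_part[[p]], idx[take + seq_len(k)])
      take <- take + k
    }
  }
  for (p in names(split)) {
    i <- idx_by_part[[p]]
    parts[[p]] <- pulse_set(pulses$values[i, , drop = FALSE],
                            pulses$label[i],
                            if (!is.null(pulses$depth_mm)) pulses$depth_mm[i])
  }
  parts
}

#' Run the full pipeline
#'
#' Simulate compression accelerometry, filter, segment and normalize pulses,
#' split stratified by label, train the chosen 1D-CNN, and evaluate it on
#' the test partition alongside the calibrated double-integration baseline.
#' Stage progress is logged to stderr.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `ccdnet_report`: metrics, counts, seeds and a
#'   config echo.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  seeds <- list(simulate = config$seed + 101L, split = config$seed + 202L,
                train = config$seed + 303L)
  spec <- build_architecture(config$model)
  scfg <- config$segmentation
  scfg$effective_points <- spec$input_length
  n <- sum(config$split)
  sim <- config$simulator
  sim$seed <- seeds$simulate
  message(sprintf("[simulate+segment] building %d labelled pulses (L=%d)",
                  n, spec$input_length))
  dataset <- make_dataset(n, config$correct_fraction, sim,
                          filter_config = config$filters,
                          segmentation_config = scfg)
  message(sprintf("[split] stratified %s", paste(config$split, collapse = "/")))
  parts <- split_pulse_set(dataset, config$split, seeds$split)
  tcfg <- config$train
  tcfg$seed <- seeds$train
  message(sprintf("[train] %s, %d iterations, batch %d", config$model,
                  tcfg$iterations, tcfg$batch_size))
  model <- train_model(spec, parts$train, parts$validation, tcfg)
  message("[evaluate] test partition")
  metrics <- evaluate_model(model, parts$test)
  baseline <- integration_baseline(parts$train, parts$test,
                                   sim$sampling_interval)
  report <- structure(list(
    model = config$model,
    n_pulses = n,
    split_sizes = vapply(parts, length, integer(1)),
    class_counts = table(dataset$label),
    cnn = list(accuracy = metrics$accuracy, f_score = metrics$f_score,
               auc = metrics$auc,
               confusion = unclass(metrics$confusion)[c("TP", "TN", "FP", "FN")]),
    integration = baseline,
    final_train_loss = tail(model$history$loss$loss, 1),
    seeds = seeds,
    config = config,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "ccdnet_report")
  report$model_fit <- model
  report
}

# calibrated double-integration baseline: fit one scale factor on the
# training split (median ratio of true depth to raw integrated displacement),
# then classify the test split by thresholding the calibrated depth
integration_baseline <- function(train_set, test_set, dt) {
  if (is.null(train_set$depth_mm) || is.null(test_set$depth_mm))
    return(NULL)
  raw_depth <- function(ps) apply(ps$values, 1, function(v)
    integrate_depth(v, dt)$depth_mm)
  d_train <- raw_depth(train_set)
  ok <- d_train > 0
  scale <- median(train_set$depth_mm[ok] / d_train[ok])
  d_test <- raw_depth(test_set) * scale
  pred <- as.integer(d_test >= 50 & d_test <= 60)
  cm <- confusion(pred, test_set$label)
  list(scale = scale, accuracy = accuracy(cm), f_score = f_score(cm),
       confusion = unclass(cm)[c("TP", "TN", "FP", "FN")])
}

#' @export
print.ccdnet_report <- function(x, ...) {
  cat(sprintf("<ccdnet_report> %s on %d pulses (split %s)\n", x$model,
              x$n_pulses, paste(x$split_sizes, collapse = "/")))
  cat(sprintf("  CNN:         ACC %.4f  F-score %.4f  AUC %.4f\n",
              x$cnn$accuracy, x$cnn$f_score, x$cnn$auc))
  if (!is.null(x$integration))
    cat(sprintf("  Integration: ACC %.4f  F-score %.4f\n",
                x$integration$accuracy, x$integration$f_score))
  cat(sprintf("  final training loss %.4f, %.1f s elapsed\n",
              x$final_train_loss, x$elapsed_s))
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report A `ccdnet_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "ccdnet_report"))
  out <- report[c("model", "n_pulses", "split_sizes", "cnn", "integration",
                  "final_train_loss", "seeds", "elapsed_s")]
  out$class_counts <- as.list(report$class_counts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
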