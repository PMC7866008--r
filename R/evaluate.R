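#' Confusion counts for binary compression-quality predictions
#'
#' Class 1 (correct compression) is the positive class: TP counts correct
#' compressions classified as correct, TN abnormal classified as abnormal,
#' FP abnormal classified as correct, FN correct classified as abnormal.
#'
#' @param predicted,actual Integer 0/1 label vectors of equal length.
#' @return An object of class `confusion_counts` with fields TP, TN, FP, FN.
#' @export
confusion <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  stopifnot(all(predicted %in% c(0, 1)), all(actual %in% c(0, 1)))
  structure(list(TP = sum(predicted == 1 & actual == 1),
                 TN = sum(predicted == 0 & actual == 0),
                 FP = sum(predicted == 1 & actual == 0),
                 FN = sum(predicted == 0 & actual == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts A [confusion()] result.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total < 1) stop("empty confusion counts")
  (counts$TP + counts$TN) / total
}

#' F-score (harmonic mean of precision and recall)
#'
#' `2 P R / (P + R)` with `P = TP / (TP + FP)` and `R = TP / (TP + FN)`;
#' returns 0 (the worst value) when TP = 0.
#'
#' @param counts A [confusion()] result.
#' @return F-score in \[0, 1\].
#' @export
f_score <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$TP + counts$FP < 1 && counts$TP + counts$FN < 1)
    stop("no positives in predictions or truth")
  if (counts$TP == 0) return(0)
  p <- counts$TP / (counts$TP + counts$FP)
  r <- counts$TP / (counts$TP + counts$FN)
  2 * p * r / (p + r)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (class-1 probabilities), true and
#' false positive rates at each threshold, and the area under the curve by
#' trapezoidal integration — which equals the normalized Mann-Whitney U
#' statistic (ties counted half).
#'
#' @param scores Numeric class-1 scores.
#' @param actual Integer 0/1 labels; both classes must be present.
#' @return An object of class `roc_curve`: list with descending `thresholds`,
#'   `tpr`, `fpr` and scalar `auc`.
#' @export
roc_auc <- function(scores, actual) {
  stopifnot(length(scores) == length(actual), all(actual %in% c(0, 1)))
  n1 <- sum(actual == 1); n0 <- sum(actual == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; a <- actual[ord]
  # group tied scores so each unique score is one threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(a == 1); fp <- cumsum(a == 0)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  thresholds <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Traditional double-integration depth estimate
#'
#' The baseline the classifier replaces: remove the quiescent baseline from
#' the cut acceleration pulse, integrate twice with the trapezoidal rule, and
#' take the peak displacement magnitude over the compression as the depth.
#' Prone to drift — white noise integrates to a random walk in velocity and
#' grows cubically in displacement variance.
#'
#' @param segment A [pulse_segment()] (or numeric vector of accelerations in
#'   m/s^2).
#' @param dt Sampling interval in seconds.
#' @param baseline Baseline acceleration to remove (default 0, i.e. already
#'   removed).
#' @param scale Optional calibration factor applied to the raw displacement
#'   (default 1).
#' @return List with `depth_mm` and `label` (1 iff depth in \[50, 60\] mm).
#' @export
integrate_depth <- function(segment, dt, baseline = 0, scale = 1) {
  a <- if (inherits(segment, "pulse_segment")) segment$samples else
    as.numeric(segment)
  if (length(a) < 3) stop("degenerate segment")
  stopifnot(dt > 0)
  a <- a - baseline
  v <- pracma::cumtrapz(seq_along(a) * dt, a)
  x <- pracma::cumtrapz(seq_along(a) * dt, as.numeric(v))
  depth_mm <- max(abs(x)) * 1000 * scale
  label <- if (depth_mm >= 50 && depth_mm <= 60) 1L else 0L
  list(depth_mm = depth_mm, label = label)
}

#' Evaluate a trained model on a labelled pulse set
#'
#' @param model A trained `ccdnet_model`.
#' @param pulses A [pulse_set()] with labels.
#' @return List with `confusion`, `accuracy`, `f_score`, `auc` and the
#'   [roc_auc()] curve.
#' @export
evaluate_model <- function(model, pulses) {
  stopifnot(inherits(pulses, "pulse_set"), !is.null(pulses$label))
  probs <- model_forward(model, pulses)
  pred <- as.integer(probs[, 2] >= 0.5)
  cm <- confusion(pred, pulses$label)
  roc <- if (length(unique(pulses$label)) == 2)
    roc_auc(probs[, 2], pulses$label)
  list(confusion = cm, accuracy = accuracy(cm), f_score = f_score(cm),
       auc = if (!is.null(roc)) roc$auc else NA_real_, roc = roc)
}
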