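# shared fixtures and independent oracles, built in code at test time

# brute-force sliding median with replicate padding
oracle_median_filter <- function(x, k) {
  h <- (k - 1) %/% 2
  padded <- c(rep(x[1], h), x, rep(x[length(x)], h))
  vapply(seq_along(x), function(i) median(padded[i:(i + k - 1)]), numeric(1))
}

# AUC as the normalized Mann-Whitney U statistic (pairwise comparisons,
# ties counted half)
oracle_auc <- function(scores, actual) {
  s1 <- scores[actual == 1]
  s0 <- scores[actual == 0]
  total <- 0
  for (a in s1) total <- total + sum(a > s0) + 0.5 * sum(a == s0)
  total / (length(s1) * length(s0))
}

# brute-force confusion tally
oracle_confusion <- function(pred, act) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && act[i] == 1) tp <- tp + 1L
    else if (pred[i] == 0 && act[i] == 0) tn <- tn + 1L
    else if (pred[i] == 1 && act[i] == 0) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# simulator settings for a linearly separable benchmark: two disjoint
# amplitude bands, no excessive class
separable_simulator <- function(seed) {
  simulator_config(seed = seed, depth_weights = c(0.5, 0.5, 0),
                   depth_ranges = list(insufficient = c(38, 44),
                                       correct = c(52, 58),
                                       excessive = c(60, 75)))
}

# recall and precision of detected segments against simulator annotations
segmentation_scores <- function(trace, config = segmentation_config()) {
  filtered <- apply_filters(trace)
  segs <- detect_pulses(trace, filtered, config)
  ann <- trace$annotations
  m <- ccdnet:::match_segments(segs, ann)
  c(recall = length(unique(m[!is.na(m)])) / nrow(ann),
    precision = sum(!is.na(m)) / max(1, length(segs)))
}
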