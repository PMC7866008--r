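#' Write an accelerometer trace as delimited text
#'
#' Two comma-separated columns (`time_s`, `accel`) at full precision, plus an
#' optional sidecar annotation file (`start,end,peak,depth_mm,label` per row,
#' 0-based half-open indices).
#'
#' @param trace An [accel_trace()].
#' @param path Output file.
#' @param annotations_path Sidecar path for annotations; default
#'   `<path>.annotations.csv` when the trace carries annotations, skipped
#'   otherwise.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, annotations_path = NULL) {
  stopifnot(inherits(trace, "accel_trace"))
  t_s <- (seq_along(trace$samples) - 1) * trace$sampling_interval
  lines <- c("time_s,accel",
             sprintf("%.17g,%.17g", t_s, trace$samples))
  writeLines(lines, path)
  if (!is.null(trace$annotations)) {
    if (is.null(annotations_path))
      annotations_path <- paste0(path, ".annotations.csv")
    a <- trace$annotations
    writeLines(c("start,end,peak,depth_mm,label",
                 sprintf("%d,%d,%d,%.17g,%d", a$start - 1L, a$end,
                         a$peak - 1L, a$depth_mm, a$label)),
               annotations_path)
  }
  invisible(path)
}

#' Read an accelerometer trace from delimited text
#'
#' Accepts two-column delimited text (time, acceleration); a non-numeric
#' first row is treated as a header and skipped. The sampling interval is
#' taken from the time column unless given.
#'
#' @param path Input file (comma, tab or whitespace separated).
#' @param sampling_interval Override the interval inferred from the time
#'   column.
#' @param annotations_path Optional sidecar annotation file (0-based
#'   half-open, as written by [write_trace()]).
#' @return An [accel_trace()].
#' @export
read_trace <- function(path, sampling_interval = NULL,
                       annotations_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty trace file: ", path)
  split_row <- function(s) strsplit(trimws(s), "[,\t ]+")[[1]]
  first <- suppressWarnings(as.numeric(split_row(lines[1])))
  start_row <- if (anyNA(first)) 2L else 1L
  if (start_row > length(lines)) stop("no data rows in ", path)
  rows <- lapply(lines[start_row:length(lines)], split_row)
  ncols <- lengths(rows)
  if (any(ncols != ncols[1]))
    stop(sprintf("ragged row at line %d of %s",
                 start_row + which(ncols != ncols[1])[1] - 1L, path))
  m <- suppressWarnings(matrix(as.numeric(unlist(rows)), ncol = ncols[1],
                               byrow = TRUE))
  if (anyNA(m))
    stop(sprintf("non-numeric cell at line %d of %s",
                 start_row + which(rowSums(is.na(m)) > 0)[1] - 1L, path))
  if (ncol(m) == 1) {
    samples <- m[, 1]
    if (is.null(sampling_interval))
      stop("single-column trace needs an explicit sampling_interval")
  } else {
    samples <- m[, 2]
    if (is.null(sampling_interval)) {
      if (nrow(m) < 2) stop("cannot infer sampling interval from one row")
      sampling_interval <- median(diff(m[, 1]))
    }
  }
  ann <- NULL
  if (!is.null(annotations_path)) {
    a <- read.table(annotations_path, header = TRUE, sep = ",")
    ann <- data.frame(start = a$start + 1L, end = a$end, peak = a$peak + 1L,
                      depth_mm = a$depth_mm, label = as.integer(a$label))
  }
  accel_trace(samples, sampling_interval, ann)
}

#' Write a pulse set
#'
#' Single-file container (RDS) holding the N x L value matrix, labels and
#' depths; [write_pulse_csv()] offers a plain-text alternative.
#'
#' @param pulses A [pulse_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pulse_set <- function(pulses, path) {
  stopifnot(inherits(pulses, "pulse_set"))
  saveRDS(unclass(pulses), path)
  invisible(path)
}

#' Read a pulse set written by [write_pulse_set()]
#' @param path Input file.
#' @return A [pulse_set()].
#' @export
read_pulse_set <- function(path) {
  x <- readRDS(path)
  pulse_set(x$values, x$label, x$depth_mm)
}

#' Export pulses as delimited text, one pulse per row
#'
#' Label and depth columns (when present) precede the waveform values.
#'
#' @param pulses A [pulse_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pulse_csv <- function(pulses, path) {
  stopifnot(inherits(pulses, "pulse_set"))
  df <- as.data.frame(pulses$values)
  names(df) <- sprintf("v%d", seq_len(ncol(pulses$values)))
  if (!is.null(pulses$depth_mm)) df <- cbind(depth_mm = pulses$depth_mm, df)
  if (!is.null(pulses$label)) df <- cbind(label = pulses$label, df)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Single-file container holding the architecture spec, parameters, running
#' statistics and training history.
#'
#' @param model A `ccdnet_model`.
#' @param path Checkpoint file.
#' @return `path` (saving) or the model (loading).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ccdnet_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  structure(x, class = "ccdnet_model")
}
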