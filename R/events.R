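# Event segmentation of raw nanopore signal.
#
# Follows the classic statistical changepoint approach of early ONT
# basecallers: a Welch t-statistic is computed between two adjacent sliding
# windows at every position; local maxima of |t| above a threshold become
# event boundaries.  Each event is summarised by 5 features used downstream:
# mean, standard deviation, length, difference of means to the previous
# event, and squared mean.

#' Event detection parameters
#'
#' @param window sliding half-window length in samples (6..9; 7 by default)
#' @param threshold minimum |t| for a boundary peak
#' @param variance_floor lower bound applied to within-window variances so a
#'   zero-variance (noiseless) window still yields a finite statistic
#' @return list of class `event_params`
#' @export
event_params <- function(window = 7L, threshold = 4.0, variance_floor = 1e-9) {
  if (window < 6L || window > 9L) stop("`window` must be in 6..9")
  if (threshold <= 0) stop("`threshold` must be > 0")
  stopifnot(variance_floor > 0)
  structure(list(window = as.integer(window), threshold = threshold,
                 variance_floor = variance_floor), class = "event_params")
}

#' Sliding-window Welch t-statistic trace
#'
#' At each boundary position p (0-based: boundary between samples p-1 and p),
#' the Welch t-statistic between `signal[p-w .. p)` and `signal[p .. p+w)` is
#' computed with both window variances floored at `variance_floor`.  Positions
#' without two full windows get 0.  The trace has one entry per sample; entry
#' i (1-based) is the statistic for a boundary before sample i.
#'
#' @param signal numeric vector, length >= 2*window
#' @param window half-window length in samples
#' @param variance_floor variance lower bound
#' @return numeric vector, same length as `signal`
#' @export
tstat_trace <- function(signal, window = 7L, variance_floor = 1e-9) {
  n <- length(signal)
  w <- as.integer(window)
  if (n < 2L * w) stop("signal shorter than two windows")
  cs <- cumsum(c(0, signal))
  cs2 <- cumsum(c(0, signal^2))
  # boundary before sample p (1-based), valid for p in (w+1) .. (n-w+1)
  p <- seq.int(w + 1L, n - w + 1L)
  s1 <- cs[p] - cs[p - w]           # left window sum
  s2 <- cs[p + w] - cs[p]           # right window sum
  q1 <- cs2[p] - cs2[p - w]
  q2 <- cs2[p + w] - cs2[p]
  m1 <- s1 / w; m2 <- s2 / w
  v1 <- pmax(q1 / w - m1^2, variance_floor)
  v2 <- pmax(q2 / w - m2^2, variance_floor)
  tv <- (m1 - m2) / sqrt(v1 / w + v2 / w)
  out <- numeric(n)
  out[p] <- tv
  out
}

#' Detect events in a raw signal
#'
#' Event boundaries are placed at local maxima of the absolute t-statistic
#' trace that exceed `threshold`, with non-maximum suppression: peaks are
#' accepted greedily in decreasing |t| order and any candidate within one
#' window of an accepted boundary is discarded.  Events tile the signal.
#'
#' @param signal numeric vector
#' @param params an `event_params`
#' @return data.frame of class `event_table` with columns `raw_start` (0-based),
#'   `raw_length`, `mean`, `stdv`, `length`, `delta_mean`, `mean_sq`
#' @export
detect_events <- function(signal, params = event_params()) {
  stopifnot(inherits(params, "event_params"))
  n <- length(signal)
  w <- params$window
  if (n < 2L * w) stop("signal shorter than two windows")
  tv <- abs(tstat_trace(signal, w, params$variance_floor))
  cand <- which(tv > params$threshold)
  # local maxima only (plateaus keep their first position)
  is_peak <- function(i) {
    left <- if (i > 1L) tv[i - 1L] else -Inf
    right <- if (i < n) tv[i + 1L] else -Inf
    tv[i] > left && tv[i] >= right
  }
  cand <- cand[vapply(cand, is_peak, logical(1L))]
  accepted <- integer(0)
  for (i in cand[order(tv[cand], decreasing = TRUE)]) {
    if (!length(accepted) || all(abs(accepted - i) >= w))
      accepted <- c(accepted, i)
  }
  # boundary before sample i (1-based) => 0-based boundary index i-1
  bounds <- sort(accepted) - 1L
  starts <- c(0L, bounds)
  ends <- c(bounds, n)
  events_from_ranges(signal, starts, ends)
}

# Build the event table (with all 5 features) from 0-based [start, end) ranges.
events_from_ranges <- function(signal, starts, ends) {
  stopifnot(length(starts) == length(ends), all(ends > starts))
  k <- length(starts)
  mean_v <- stdv_v <- numeric(k)
  for (i in seq_len(k)) {
    seg <- signal[(starts[i] + 1L):ends[i]]
    mean_v[i] <- mean(seg)
    stdv_v[i] <- sqrt(mean((seg - mean_v[i])^2))  # population sd; length-1 -> 0
  }
  len_v <- as.integer(ends - starts)
  delta <- c(0, mean_v[-k] - mean_v[-1L])  # previous minus current; first = 0
  if (k == 1L) delta <- 0
  structure(data.frame(raw_start = as.integer(starts), raw_length = len_v,
                       mean = mean_v, stdv = stdv_v, length = len_v,
                       delta_mean = delta, mean_sq = mean_v^2),
            class = c("event_table", "data.frame"))
}

#' Extract the 5-feature matrix from an event table
#'
#' Column order: mean, stdv, length, delta_mean (previous minus current, 0 for
#' the first event), mean squared.
#'
#' @param events an `event_table`
#' @return numeric matrix (events x 5)
#' @export
featurize <- function(events) {
  if (NROW(events) == 0L)
    return(matrix(numeric(0), 0L, 5L,
                  dimnames = list(NULL, EVENT_FEATURES)))
  m <- as.matrix(events[, c("mean", "stdv", "length", "delta_mean", "mean_sq")])
  colnames(m) <- EVENT_FEATURES
  m
}

EVENT_FEATURES <- c("mean", "stdv", "length", "delta_mean", "mean_sq")

#' Write events to TSV
#' @param events an `event_table`
#' @param read_id identifier recorded in the first column
#' @param path output file
#' @export
write_events_tsv <- function(events, read_id, path) {
  df <- cbind(read_id = read_id, as.data.frame(events))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
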