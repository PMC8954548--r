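# Sample construction and batching.
#
# A sample is a window of consecutive events whose raw span holds at most
# `rawmax` raw values; consecutive samples start `eventoffset` events apart so
# they may overlap.  Target base sequences are the bases whose ground-truth
# raw range is fully contained in the sample's raw span, wrapped in START/END
# tokens.  Standardisation uses 6 scalers (1 raw + 5 event features) fitted on
# the training split only; batches carry explicit masks over the padding.

#' Token vocabulary
#'
#' Fixed 7-symbol vocabulary: PAD, START, END and the 4 nucleotides, with
#' integer ids PAD=0, START=1, END=2, A=3, C=4, G=5, T=6.
#' @return named integer vector of class `tokenizer`
#' @export
tokenizer <- function() {
  structure(c(PAD = 0L, START = 1L, END = 2L, A = 3L, C = 4L, G = 5L, T = 6L),
            class = "tokenizer")
}

VOCAB_SIZE <- 7L
TOK_PAD <- 0L; TOK_START <- 1L; TOK_END <- 2L; TOK_BASE0 <- 3L

#' Tokenize a base string
#'
#' Wraps the per-base tokens in START/END markers.
#' @param bases character scalar over A/C/G/T (may be empty)
#' @return integer token vector `c(START, ..., END)`
#' @export
tokenize <- function(bases) {
  stopifnot(is.character(bases), length(bases) == 1L)
  if (nchar(bases) == 0L) return(c(TOK_START, TOK_END))
  ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
  ids <- match(ch, c("A", "C", "G", "T"))
  if (anyNA(ids)) stop("unknown symbol in base sequence: ",
                       paste(unique(ch[is.na(ids)]), collapse = ","))
  c(TOK_START, ids + TOK_BASE0 - 1L, TOK_END)
}

#' Convert tokens back to a base string
#'
#' Strips START/END/PAD markers; inverse of [tokenize()].
#' @param tokens integer vector of token ids
#' @return character scalar
#' @export
detokenize <- function(tokens) {
  if (any(tokens < 0L | tokens >= VOCAB_SIZE)) stop("invalid token id")
  keep <- tokens >= TOK_BASE0
  paste0(c("A", "C", "G", "T")[tokens[keep] - TOK_BASE0 + 1L], collapse = "")
}

#' Build overlapping samples from a read and its events
#'
#' Sample i starts at event `1 + i*eventoffset` and greedily accumulates
#' consecutive events while the cumulative raw length stays within `rawmax`
#' and the event count within `eventmax`.  When the read carries ground-truth
#' ranges, the target is every base whose raw range is fully contained in the
#' sample's raw span.  A start event longer than `rawmax` is skipped with a
#' warning.
#'
#' @param read a `raw_read` (truth ranges optional: set to NULL for inference)
#' @param events an `event_table` tiling `read$signal`
#' @param rawmax maximum raw values per sample
#' @param eventmax maximum events per sample
#' @param eventoffset stride between consecutive sample start events (>= 1)
#' @return list of samples; each a list with `raw_values`, `raw_len`,
#'   `event_features` (matrix k x 5), `event_count`, `raw_span`
#'   (0-based half-open), `tokens` (NULL when no truth), `bases`
#' @export
build_samples <- function(read, events, rawmax = 200L, eventmax = 30L,
                          eventoffset = 1L) {
  stopifnot(eventoffset >= 1L, NROW(events) >= 1L)
  n_ev <- NROW(events)
  ev_len <- events$raw_length
  ev_start <- events$raw_start
  feats <- featurize(events)
  truth <- read$truth_ranges
  samples <- list()
  starts <- seq.int(1L, n_ev, by = as.integer(eventoffset))
  for (s in starts) {
    if (ev_len[s] > rawmax) {
      warning(sprintf("event %d longer than rawmax (%d > %d); sample skipped",
                      s, ev_len[s], rawmax))
      next
    }
    e <- s
    tot <- ev_len[s]
    while (e < n_ev && (e - s + 1L) < eventmax &&
           tot + ev_len[e + 1L] <= rawmax) {
      e <- e + 1L
      tot <- tot + ev_len[e]
    }
    span0 <- ev_start[s]
    span1 <- ev_start[e] + ev_len[e]
    bases <- NULL
    toks <- NULL
    if (!is.null(truth)) {
      inside <- truth$raw_start >= span0 & truth$raw_end <= span1
      bases <- paste0(truth$base[inside], collapse = "")
      toks <- tokenize(bases)
    }
    samples[[length(samples) + 1L]] <- list(
      raw_values = read$signal[(span0 + 1L):span1],
      raw_len = as.integer(tot),
      event_features = feats[s:e, , drop = FALSE],
      event_count = e - s + 1L,
      raw_span = c(span0, span1),
      start_event = s,
      tokens = toks,
      bases = bases)
  }
  samples
}

#' Shuffle and split samples into test / validation / train sets
#'
#' @param samples list of samples
#' @param fractions numeric length-3 vector `(test, validation, train)` summing
#'   to 1
#' @param seed integer seed; the split is deterministic given the seed
#' @return list with elements `test`, `validation`, `train`
#' @export
split_dataset <- function(samples, fractions = c(0.15, 0.15, 0.70), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be 3 non-negative numbers summing to 1")
  }
  n <- length(samples)
  perm <- with_seed(seed, sample.int(n))
  cuts <- round(cumsum(fractions) * n)
  idx_test <- perm[seq_len(cuts[1L])]
  idx_val <- perm[setdiff(seq_len(cuts[2L]), seq_len(cuts[1L]))]
  idx_train <- perm[setdiff(seq_len(n), seq_len(cuts[2L]))]
  list(test = samples[idx_test], validation = samples[idx_val],
       train = samples[idx_train])
}

#' Fit the 6 standardisation scalers on training samples
#'
#' One (mean, sd) pair for raw values pooled over all training samples and one
#' per event feature.  Standard deviations are floored so constant features
#' scale to zero rather than dividing by zero.
#'
#' @param train_samples list of samples (training split only)
#' @param sd_floor minimum standard deviation
#' @return object of class `scaler_set`
#' @export
fit_scalers <- function(train_samples, sd_floor = 1e-8) {
  stopifnot(length(train_samples) > 0L)
  raw_all <- unlist(lapply(train_samples, `[[`, "raw_values"))
  ev_all <- do.call(rbind, lapply(train_samples, `[[`, "event_features"))
  mu <- c(mean(raw_all), colMeans(ev_all))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sdv <- c(pop_sd(raw_all), apply(ev_all, 2L, pop_sd))
  sdv[!is.finite(sdv)] <- 0
  sdv <- pmax(sdv, sd_floor)
  structure(list(mean = mu, sd = sdv,
                 names = c("raw", EVENT_FEATURES)),
            class = "scaler_set")
}

#' Standardise samples with a fitted scaler set
#'
#' @param samples list of samples
#' @param scalers a `scaler_set` fitted on the training split
#' @return samples with `raw_values` and `event_features` standardised
#' @export
apply_scalers <- function(samples, scalers) {
  stopifnot(inherits(scalers, "scaler_set"))
  lapply(samples, function(s) {
    s$raw_values <- (s$raw_values - scalers$mean[1L]) / scalers$sd[1L]
    s$event_features <- sweep(
      sweep(s$event_features, 2L, scalers$mean[-1L], "-"),
      2L, scalers$sd[-1L], "/")
    s
  })
}

#' Gather samples into padded, masked batches
#'
#' Raw vectors are padded (with 0) or truncated to `rawmax`, event feature
#' matrices to `eventmax` rows, and token targets to the longest target in the
#' sample set.  Masks mark the non-padding prefix of each row.
#'
#' @param samples scaled, tokenized samples
#' @param batch_size samples per batch (last batch may be smaller)
#' @param rawmax,eventmax padding lengths
#' @param target_len pad targets to this many tokens (default: longest seen)
#' @return list of batches; each a list with `raw` (B x rawmax), `raw_mask`,
#'   `events` (B x eventmax x 5), `event_mask`, `target` (B x T or NULL),
#'   `target_mask`, `n`
#' @export
make_batches <- function(samples, batch_size = 128L, rawmax = 200L,
                         eventmax = 30L, target_len = NULL) {
  n <- length(samples)
  stopifnot(n > 0L)
  has_targets <- !is.null(samples[[1L]]$tokens)
  if (has_targets && is.null(target_len))
    target_len <- max(vapply(samples, function(s) length(s$tokens), 1L))
  starts <- seq.int(1L, n, by = as.integer(batch_size))
  lapply(starts, function(s0) {
    idx <- s0:min(s0 + batch_size - 1L, n)
    b <- length(idx)
    raw <- matrix(0, b, rawmax)
    raw_mask <- matrix(0, b, rawmax)
    ev <- array(0, c(b, eventmax, 5L))
    ev_mask <- matrix(0, b, eventmax)
    tgt <- if (has_targets) matrix(TOK_PAD, b, target_len) else NULL
    tgt_mask <- if (has_targets) matrix(0, b, target_len) else NULL
    for (i in seq_len(b)) {
      s <- samples[[idx[i]]]
      rl <- min(s$raw_len, rawmax)
      raw[i, seq_len(rl)] <- s$raw_values[seq_len(rl)]
      raw_mask[i, seq_len(rl)] <- 1
      ec <- min(s$event_count, eventmax)
      ev[i, seq_len(ec), ] <- s$event_features[seq_len(ec), , drop = FALSE]
      ev_mask[i, seq_len(ec)] <- 1
      if (has_targets) {
        tl <- min(length(s$tokens), target_len)
        tgt[i, seq_len(tl)] <- s$tokens[seq_len(tl)]
        tgt_mask[i, seq_len(tl)] <- 1
      }
    }
    list(raw = raw, raw_mask = raw_mask, events = ev, event_mask = ev_mask,
         target = tgt, target_mask = tgt_mask, n = b)
  })
}

#' One-call dataset preparation
#'
#' Detects events, builds samples for every read, shuffles/splits, fits the
#' scalers on the training split and standardises all three splits.
#'
#' @param reads list of `raw_read`
#' @param params an `event_params`
#' @param rawmax,eventmax,eventoffset sample construction parameters
#' @param fractions split fractions `(test, validation, train)`
#' @param seed integer seed for the shuffle
#' @return list with `train`, `validation`, `test` (scaled sample lists),
#'   `scalers`, and `target_len` (longest training target, plus headroom)
#' @export
prepare_dataset <- function(reads, params = event_params(), rawmax = 200L,
                            eventmax = 30L, eventoffset = 1L,
                            fractions = c(0.15, 0.15, 0.70), seed = 1L) {
  samples <- list()
  for (read in reads) {
    ev <- detect_events(read$signal, params)
    samples <- c(samples, build_samples(read, ev, rawmax, eventmax,
                                        eventoffset))
  }
  # drop samples with empty targets (window contains no fully-covered base)
  keep <- vapply(samples, function(s) is.null(s$tokens) ||
                   length(s$tokens) > 2L, logical(1L))
  samples <- samples[keep]
  splits <- split_dataset(samples, fractions, seed = seed)
  scalers <- fit_scalers(splits$train)
  target_len <- max(vapply(splits$train, function(s) length(s$tokens), 1L)) + 2L
  list(train = apply_scalers(splits$train, scalers),
       validation = apply_scalers(splits$validation, scalers),
       test = apply_scalers(splits$test, scalers),
       scalers = scalers, target_len = target_len)
}
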