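# Read assembly and accuracy evaluation.
#
# Per-sample predictions are merged into a whole read with pairwise global
# (Needleman-Wunsch) alignment of each new prediction against the tail of the
# growing consensus: inside the aligned overlap the earlier consensus base
# wins, and the part of the new prediction extending past the consensus end
# is appended.  Read accuracy is the "BLAST identity": alignment matches
# divided by total alignment length including insertions and deletions;
# identities from multiple reads are averaged weighted by aligned block
# length.

#' Global (Needleman-Wunsch) alignment with linear gap penalty
#'
#' Deterministic traceback preferring diagonal over up (gap in `b`) over left
#' (gap in `a`).
#'
#' @param a,b sequences to align (character scalars; may be empty)
#' @param match,mismatch,gap scoring scheme (defaults +1/-1/-1)
#' @return list of class `alignment_result`: `aligned_a`, `aligned_b` (with
#'   `-` gap symbols), `score`, `matches`, `alignment_length`
#' @export
needleman_wunsch <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  av <- if (nchar(a)) strsplit(a, "", fixed = TRUE)[[1L]] else character(0)
  bv <- if (nchar(b)) strsplit(b, "", fixed = TRUE)[[1L]] else character(0)
  n <- length(av); m <- length(bv)
  # score matrix F (n+1 x m+1); traceback code: 1 diag, 2 up (consume a),
  # 3 left (consume b)
  F <- matrix(0, n + 1L, m + 1L)
  P <- matrix(0L, n + 1L, m + 1L)
  F[, 1L] <- gap * (0:n); P[, 1L][-1L] <- 2L
  F[1L, ] <- gap * (0:m); P[1L, ][-1L] <- 3L
  if (n > 0L && m > 0L) {
    for (i in seq_len(n)) {
      sub <- ifelse(bv == av[i], match, mismatch)
      for (j in seq_len(m)) {
        d <- F[i, j] + sub[j]
        u <- F[i, j + 1L] + gap
        l <- F[i + 1L, j] + gap
        if (d >= u && d >= l) { F[i + 1L, j + 1L] <- d; P[i + 1L, j + 1L] <- 1L }
        else if (u >= l)      { F[i + 1L, j + 1L] <- u; P[i + 1L, j + 1L] <- 2L }
        else                  { F[i + 1L, j + 1L] <- l; P[i + 1L, j + 1L] <- 3L }
      }
    }
  }
  i <- n + 1L; j <- m + 1L
  ra <- character(0); rb <- character(0)
  while (i > 1L || j > 1L) {
    mv <- P[i, j]
    if (mv == 1L) {
      ra <- c(av[i - 1L], ra); rb <- c(bv[j - 1L], rb); i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      ra <- c(av[i - 1L], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j - 1L], rb); j <- j - 1L
    }
  }
  matches <- sum(ra == rb & ra != "-")
  structure(list(aligned_a = paste0(ra, collapse = ""),
                 aligned_b = paste0(rb, collapse = ""),
                 score = F[n + 1L, m + 1L],
                 matches = as.integer(matches),
                 alignment_length = length(ra)),
            class = "alignment_result")
}

# Suffix-prefix overlap alignment (semi-global NW): leading tail positions
# may be skipped for free and the trailing part of `nxt` is left unaligned.
# Returns the number of leading `nxt` characters that align onto the tail
# (the rest is the novel suffix) and the overlap score.
overlap_align <- function(tail_part, nxt, match = 1, mismatch = -1,
                          gap = -1, expected = NULL, slack = NULL) {
  av <- if (nchar(tail_part)) strsplit(tail_part, "", TRUE)[[1L]] else
    character(0)
  bv <- if (nchar(nxt)) strsplit(nxt, "", TRUE)[[1L]] else character(0)
  n <- length(av); m <- length(bv)
  if (n == 0L || m == 0L) return(list(consumed = 0L, score = 0))
  prev <- gap * (0:m)  # row i = 0: skipping nxt prefix is penalised
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- 0  # skipping tail prefix is free
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      cur[j + 1L] <- max(prev[j] + sub[j], prev[j + 1L] + gap,
                         cur[j] + gap)
    }
    prev <- cur
  }
  # prev[j + 1] is the best score consuming j leading nxt characters while
  # spanning the whole tail.  With low-complexity (periodic) sequences the
  # unconstrained optimum is ambiguous, so when the caller knows the
  # expected overlap (from the samples' raw spans) the split point is
  # searched only inside a window around it; ties prefer the split closest
  # to the expectation, then the longer overlap.
  js <- 0:m
  if (!is.null(expected)) {
    if (is.null(slack)) slack <- max(3L, ceiling(0.3 * m))
    js <- js[js >= expected - slack & js <= expected + slack]
    if (!length(js)) js <- 0:m
  }
  sc <- prev[js + 1L]
  best <- js[order(-sc, if (!is.null(expected)) abs(js - expected) else -js)]
  consumed <- best[1L]
  list(consumed = as.integer(consumed), score = prev[consumed + 1L])
}

#' Merge ordered per-sample predictions into one read
#'
#' Predictions must be ordered by sample start position.  Each prediction is
#' aligned against the tail of the growing consensus with a semi-global
#' (free-end-gap) Needleman-Wunsch variant that finds the best
#' suffix-prefix overlap; within the aligned overlap the consensus (earlier)
#' base is kept, and the unaligned suffix of the new prediction is appended.
#' Empty predictions are skipped with a message.
#'
#' @param predictions character vector of base strings, in sample order
#' @param read_id identifier for the assembled read
#' @param tail_window how much consensus tail to align against (default
#'   2 x the longest prediction, for near-linear assembly)
#' @param expected_overlap optional numeric vector (one entry per junction,
#'   i.e. `length(predictions) - 1`): expected number of leading bases of
#'   each next prediction that overlap the consensus, typically derived from
#'   the samples' raw spans or attention positions.  Resolves the
#'   registration ambiguity of low-complexity sequences; NA entries fall
#'   back to the unconstrained optimum
#' @param overlap_slack half-width of the split-point search window around
#'   each expectation (default: max(3, 30% of the prediction length))
#' @return object of class `assembled_read`: list with `read_id`, `sequence`,
#'   `n_samples`
#' @export
merge_samples <- function(predictions, read_id = "read", tail_window = NULL,
                          expected_overlap = NULL, overlap_slack = NULL) {
  if (!length(predictions)) stop("no predictions to merge")
  if (!is.null(expected_overlap) &&
      length(expected_overlap) != length(predictions) - 1L)
    stop("`expected_overlap` needs one entry per junction")
  empty <- !nchar(predictions)
  if (any(empty)) {
    message(sprintf("skipping %d empty prediction(s)", sum(empty)))
    predictions <- predictions[!empty]
    if (!is.null(expected_overlap))  # junction expectations no longer valid
      expected_overlap <- NULL
  }
  if (!length(predictions)) {
    return(structure(list(read_id = read_id, sequence = "", n_samples = 0L),
                     class = "assembled_read"))
  }
  if (is.null(tail_window)) tail_window <- 2L * max(nchar(predictions))
  consensus <- predictions[1L]
  for (k in seq_along(predictions)[-1L]) {
    nxt <- predictions[k]
    tl <- min(nchar(consensus), tail_window)
    tail_part <- substr(consensus, nchar(consensus) - tl + 1L,
                        nchar(consensus))
    exp_k <- if (!is.null(expected_overlap) &&
                 is.finite(expected_overlap[k - 1L]))
      as.integer(round(expected_overlap[k - 1L])) else NULL
    ov <- overlap_align(tail_part, nxt, expected = exp_k,
                        slack = overlap_slack)
    suffix <- if (ov$consumed < nchar(nxt))
      substr(nxt, ov$consumed + 1L, nchar(nxt)) else ""
    consensus <- paste0(consensus, suffix)
  }
  structure(list(read_id = read_id, sequence = consensus,
                 n_samples = length(predictions)),
            class = "assembled_read")
}

#' @export
print.assembled_read <- function(x, ...) {
  cat(sprintf("<assembled_read> %s: %d bases from %d samples\n",
              x$read_id, nchar(x$sequence), x$n_samples))
  invisible(x)
}

#' Subset (exact-match) accuracy
#'
#' Fraction of positions whose base matches exactly at the same position;
#' the denominator is the longer of the two sequences.  Two empty sequences
#' score 1.
#'
#' @param pred,truth base strings (no START/END/PAD markers)
#' @return fraction in [0, 1]
#' @export
subset_accuracy <- function(pred, truth) {
  np <- nchar(pred); nt <- nchar(truth)
  if (np == 0L && nt == 0L) return(1)
  if (np == 0L || nt == 0L) return(0)
  k <- min(np, nt)
  pv <- strsplit(substr(pred, 1L, k), "", fixed = TRUE)[[1L]]
  tv <- strsplit(substr(truth, 1L, k), "", fixed = TRUE)[[1L]]
  sum(pv == tv) / max(np, nt)
}

#' Read accuracy ("BLAST identity") of an assembled read
#'
#' Globally aligns the read to its reference; identity is matches divided by
#' the total alignment length (columns, including insertions and deletions),
#' and the aligned block length is that column count.
#'
#' @param read an `assembled_read` (or a plain base string)
#' @param reference reference base string
#' @return list with `identity` (fraction) and `block_length`
#' @export
read_accuracy <- function(read, reference) {
  seq <- if (inherits(read, "assembled_read")) read$sequence else read
  if (!nchar(seq) || !nchar(reference)) stop("read and reference must be nonempty")
  al <- needleman_wunsch(seq, reference)
  list(identity = al$matches / al$alignment_length,
       block_length = al$alignment_length)
}

#' Length-weighted mean identity over reads
#'
#' @param identities per-read identity fractions
#' @param block_lengths per-read aligned block lengths (weights)
#' @return weighted mean identity
#' @export
weighted_identity <- function(identities, block_lengths) {
  stopifnot(length(identities) == length(block_lengths),
            length(identities) > 0L)
  sum(identities * block_lengths) / sum(block_lengths)
}

#' Evaluate assembled reads against references
#'
#' @param reads list of `assembled_read`
#' @param references named character vector (names = read ids)
#' @return list of class `accuracy_report`: per-read data.frame and the
#'   weighted mean identity
#' @export
evaluate_reads <- function(reads, references) {
  rows <- lapply(reads, function(r) {
    ref <- references[[r$read_id]]
    if (is.null(ref)) stop("no reference for read ", r$read_id)
    ra <- read_accuracy(r, ref)
    data.frame(read_id = r$read_id, identity = ra$identity,
               block_length = ra$block_length, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(per_read = tab,
                 weighted_identity = weighted_identity(tab$identity,
                                                       tab$block_length)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %d reads, weighted identity %.3f%%\n",
              nrow(x$per_read), 100 * x$weighted_identity))
  invisible(x)
}

#' Summarise a model x dataset x beam-width accuracy table
#'
#' Given per-cell read accuracies (long format), computes the mean
#' improvement of a wider beam over greedy decoding - over all models and
#' over a subset of modes - and the mean advantage of one mode over another,
#' overall and restricted to the wide-beam cells.  This is the arithmetic
#' used to compare decoding strategies and model variants in an evaluation
#' report.
#'
#' @param tbl data.frame with columns `dataset`, `mode`, `beam_width`,
#'   `accuracy` (percent or fraction; differences come out in the same unit)
#' @param wide_width the non-greedy beam width present in the table
#' @param improved_modes modes over which the restricted beam improvement is
#'   averaged
#' @param better,worse modes compared in the mode-advantage summary
#' @return list with `beam_improvement_all`, `beam_improvement_restricted`,
#'   `mode_advantage_all`, `mode_advantage_wide`
#' @export
accuracy_comparison_summary <- function(tbl, wide_width = 5L,
                                        improved_modes = c("raw", "joint"),
                                        better = "joint", worse = "raw") {
  stopifnot(all(c("dataset", "mode", "beam_width", "accuracy") %in%
                  names(tbl)))
  wide <- tbl[tbl$beam_width == wide_width, ]
  narrow <- tbl[tbl$beam_width == 1L, ]
  key <- function(d) paste(d$dataset, d$mode)
  imp <- wide$accuracy - narrow$accuracy[match(key(wide), key(narrow))]
  names(imp) <- key(wide)
  adv_tbl <- tbl[tbl$mode == better, ]
  key2 <- function(d) paste(d$dataset, d$beam_width)
  base <- tbl[tbl$mode == worse, ]
  adv <- adv_tbl$accuracy - base$accuracy[match(key2(adv_tbl), key2(base))]
  wide_cells <- adv_tbl$beam_width == wide_width
  list(beam_improvement_all = mean(imp),
       beam_improvement_restricted = mean(imp[wide$mode %in% improved_modes]),
       mode_advantage_all = mean(adv),
       mode_advantage_wide = mean(adv[wide_cells]))
}
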