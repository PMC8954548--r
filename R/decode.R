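# Greedy and beam-search decoding, and attention-weight export.
#
# Both decoders emit only A/C/G/T/END (PAD and START are masked out of the
# output distribution so the contract "output contains no PAD/START" holds by
# construction).  Beam search accumulates per-token log-probabilities with no
# length normalisation; hypotheses are retired when they emit END and ties
# are broken by lower token id, then earlier finish.

EMIT_MASK <- c(-Inf, -Inf, 0, 0, 0, 0, 0)  # forbid PAD and START emissions

#' Greedy decoding of a batch
#'
#' Starts every sample at START and repeatedly feeds back the argmax token
#' until END or the length cap.
#'
#' @param model a `squiggle_model`
#' @param enc an `encoder_outputs`
#' @param max_len decoding cap in emitted tokens (model default if NULL)
#' @param keep_attention also return the per-step attention weight rows
#' @return list per sample: `tokens` (emitted ids, END included when reached),
#'   `logprob` (summed token log-probability), and `attention` (steps x S
#'   matrix) when requested
#' @export
greedy_decode <- function(model, enc, max_len = NULL,
                          keep_attention = FALSE) {
  if (is.null(max_len)) max_len <- model$config$decode_max
  B <- enc$B
  state <- decoder_init(model, B)
  prev <- rep(TOK_START, B)
  done <- rep(FALSE, B)
  toks <- vector("list", B)
  lps <- numeric(B)
  att <- if (keep_attention) replicate(B, NULL, simplify = FALSE)
  for (t in seq_len(max_len)) {
    ds <- decode_step(model, prev, state, enc)
    state <- ds$state
    lg <- ds$logits + rep(EMIT_MASK, each = B)
    lp <- log_softmax(lg)
    nxt <- max.col(lg, ties.method = "first") - 1L
    for (i in which(!done)) {
      toks[[i]] <- c(toks[[i]], nxt[i])
      lps[i] <- lps[i] + lp[i, nxt[i] + 1L]
      if (keep_attention) att[[i]] <- rbind(att[[i]], ds$alpha[i, ])
      if (nxt[i] == TOK_END) done[i] <- TRUE
    }
    if (all(done)) break
    prev <- nxt
  }
  out <- lapply(seq_len(B), function(i) {
    r <- list(tokens = toks[[i]], logprob = lps[i])
    if (keep_attention) r$attention <- att[[i]]
    r
  })
  out
}

# Replicate a single-sample encoder output k times along the batch axis.
enc_replicate <- function(enc, k) {
  stopifnot(enc$B == 1L)
  S <- enc$S
  Hk <- enc$Hflat[rep(seq_len(S), each = k), , drop = FALSE]
  structure(list(Hflat = Hk,
                 mask = enc$mask[rep(1L, k), , drop = FALSE],
                 B = k, S = S, S_raw = enc$S_raw, S_evt = enc$S_evt,
                 D = enc$D, cache = NULL),
            class = "encoder_outputs")
}

#' Beam-search decoding of a single sample
#'
#' Standard beam search over summed token log-probabilities.  At each step
#' every alive hypothesis is expanded over the 5 permitted tokens
#' (A/C/G/T/END), the best `width` continuations survive, and hypotheses
#' emitting END are retired.  The best finished hypothesis (highest score;
#' ties: earlier finish, then lexicographically smaller token ids) is
#' returned; with `width = 1` this is exactly greedy decoding.
#'
#' @param model a `squiggle_model`
#' @param enc an `encoder_outputs` with `B = 1`
#' @param width beam width (>= 1)
#' @param max_len decoding cap in emitted tokens
#' @return list with `tokens` and `logprob`
#' @export
beam_decode <- function(model, enc, width = 5L, max_len = NULL) {
  if (width < 1L) stop("`width` must be >= 1")
  if (enc$B != 1L) stop("beam_decode expects a single-sample encoding")
  if (is.null(max_len)) max_len <- model$config$decode_max
  H <- model$config$latent_dim
  alive <- list(list(tokens = integer(0), score = 0,
                     state = decoder_init(model, 1L), prev = TOK_START))
  finished <- list()
  for (t in seq_len(max_len)) {
    k <- length(alive)
    if (k == 0L) break
    enck <- enc_replicate(enc, k)
    state <- list(
      h = do.call(rbind, lapply(alive, function(a) a$state$h)),
      c = do.call(rbind, lapply(alive, function(a) a$state$c)),
      htilde = do.call(rbind, lapply(alive, function(a) a$state$htilde)))
    prev <- vapply(alive, function(a) a$prev, 0L)
    ds <- decode_step(model, prev, state, enck)
    lp <- log_softmax(ds$logits + rep(EMIT_MASK, each = k))
    # candidate table: every (hypothesis, token) continuation
    cand_hyp <- rep(seq_len(k), times = VOCAB_SIZE)
    cand_tok <- rep(seq_len(VOCAB_SIZE) - 1L, each = k)
    cand_score <- vapply(seq_along(cand_hyp), function(j)
      alive[[cand_hyp[j]]]$score + lp[cand_hyp[j], cand_tok[j] + 1L], 0)
    keep <- is.finite(cand_score)
    cand_hyp <- cand_hyp[keep]; cand_tok <- cand_tok[keep]
    cand_score <- cand_score[keep]
    ord <- order(-cand_score, cand_tok, cand_hyp)
    take <- utils::head(ord, width)
    new_alive <- list()
    for (j in take) {
      hyp <- alive[[cand_hyp[j]]]
      tok <- cand_tok[j]
      ext <- list(tokens = c(hyp$tokens, tok), score = cand_score[j],
                  state = list(h = ds$state$h[cand_hyp[j], , drop = FALSE],
                               c = ds$state$c[cand_hyp[j], , drop = FALSE],
                               htilde = ds$state$htilde[cand_hyp[j], ,
                                                        drop = FALSE]),
                  prev = tok, finish_step = t)
      if (tok == TOK_END) finished[[length(finished) + 1L]] <- ext
      else new_alive[[length(new_alive) + 1L]] <- ext
    }
    alive <- new_alive
  }
  pool <- c(finished, alive)  # unfinished hypotheses only matter at the cap
  stopifnot(length(pool) > 0L)
  scores <- vapply(pool, function(h) h$score, 0)
  fsteps <- vapply(pool, function(h)
    if (is.null(h$finish_step)) Inf else h$finish_step, 0)
  keys <- vapply(pool, function(h)
    paste(sprintf("%02d", h$tokens), collapse = ""), "")
  best <- order(-scores, fsteps, keys)[1L]
  list(tokens = pool[[best]]$tokens, logprob = pool[[best]]$score)
}

#' Export attention weights for a decoded sample
#'
#' Runs greedy decoding on a single-sample encoding and returns the attention
#' weight matrix: one row per emitted token, one column per encoder step (in
#' joint mode the raw block first, then the event block).  Rows sum to 1 and
#' padded columns are exactly zero.
#'
#' @param model a `squiggle_model`
#' @param enc an `encoder_outputs` with `B = 1`
#' @param max_len decoding cap
#' @return numeric matrix (emitted tokens x S)
#' @export
export_attention <- function(model, enc, max_len = NULL) {
  stopifnot(enc$B == 1L)
  g <- greedy_decode(model, enc, max_len, keep_attention = TRUE)[[1L]]
  att <- g$attention
  rownames(att) <- NULL
  att
}

# Attention rows for a fixed emitted token sequence (single sample):
# re-runs the decoder feeding `tokens` and collects the alpha vectors.
attention_for_tokens <- function(model, enc, tokens) {
  state <- decoder_init(model, 1L)
  prev <- TOK_START
  att <- matrix(0, length(tokens), enc$S)
  for (i in seq_along(tokens)) {
    ds <- decode_step(model, prev, state, enc)
    att[i, ] <- ds$alpha
    state <- ds$state
    prev <- tokens[i]
  }
  att
}

# Absolute raw-coordinate position map for one sample's encoder steps: raw
# block columns map to consecutive raw coordinates of the sample span; event
# block columns map to event centres.  Used to anchor assembly.
sample_position_map <- function(model, sample, events) {
  cfg <- model$config
  pos <- numeric(0)
  if (cfg$mode %in% c("raw", "joint")) {
    p <- rep(0, cfg$rawmax)
    rl <- min(sample$raw_len, cfg$rawmax)
    p[seq_len(rl)] <- sample$raw_span[1L] + seq_len(rl) - 1L
    pos <- c(pos, p)
  }
  if (cfg$mode %in% c("event", "joint")) {
    p <- rep(0, cfg$eventmax)
    ec <- min(sample$event_count, cfg$eventmax)
    idx <- sample$start_event + seq_len(ec) - 1L
    p[seq_len(ec)] <- events$raw_start[idx] + events$raw_length[idx] / 2
    pos <- c(pos, p)
  }
  pos
}

# Per-base attended raw positions: alpha rows (one per emitted base) times
# the position map.
attended_positions <- function(att, pos) as.vector(att %*% pos)

#' Basecall one read
#'
#' Full inference path: event detection, sample construction with the given
#' stride, scaling with the training scalers, greedy or beam decoding of
#' every sample, and pairwise merging of the per-sample predictions with
#' the overlap at each junction anchored by the decoder's attention (each
#' emitted base is assigned the raw coordinate its attention points at, and
#' bases attending before the previous sample's span end are treated as
#' overlap).
#'
#' @param model a `squiggle_model`
#' @param signal raw signal vector
#' @param scalers `scaler_set` fitted at training time
#' @param params event detection parameters
#' @param eventoffset sample stride in events (6 is the read-accuracy default)
#' @param beam_width 1 = greedy
#' @param read_id identifier for the assembled read
#' @return an `assembled_read` (see [merge_samples()])
#' @export
basecall_read <- function(model, signal, scalers, params = event_params(),
                          eventoffset = 6L, beam_width = 1L,
                          read_id = "read") {
  cfg <- model$config
  ev <- detect_events(signal, params)
  read <- list(signal = signal, truth_ranges = NULL)
  samples <- build_samples(read, ev, cfg$rawmax, cfg$eventmax, eventoffset)
  if (!length(samples)) stop("no samples could be built from the signal")
  raw_samples <- samples  # unscaled copies keep span/event bookkeeping
  samples <- apply_scalers(samples, scalers)
  n <- length(samples)
  preds <- character(n)
  positions <- vector("list", n)  # attended raw coordinate per emitted base
  if (beam_width == 1L) {
    batches <- make_batches(samples, 128L, cfg$rawmax, cfg$eventmax)
    k <- 0L
    for (b in batches) {
      dec <- greedy_decode(model, encode(model, b), keep_attention = TRUE)
      for (i in seq_len(b$n)) {
        k <- k + 1L
        toks <- dec[[i]]$tokens
        preds[k] <- detokenize(toks)
        pmap <- sample_position_map(model, raw_samples[[k]], ev)
        pp <- attended_positions(dec[[i]]$attention, pmap)
        positions[[k]] <- pp[toks >= TOK_BASE0]
      }
    }
  } else {
    for (i in seq_len(n)) {
      b <- make_batches(samples[i], 1L, cfg$rawmax, cfg$eventmax)[[1L]]
      enc1 <- encode(model, b)
      bd <- beam_decode(model, enc1, width = beam_width)
      preds[i] <- detokenize(bd$tokens)
      att <- attention_for_tokens(model, enc1, bd$tokens)
      pmap <- sample_position_map(model, raw_samples[[i]], ev)
      pp <- attended_positions(att, pmap)
      positions[[i]] <- pp[bd$tokens >= TOK_BASE0]
    }
  }
  keep <- nchar(preds) > 0L
  preds <- preds[keep]
  if (!length(preds)) stop("all sample predictions were empty")
  positions <- positions[keep]
  spans <- do.call(rbind, lapply(raw_samples[keep], `[[`, "raw_span"))
  # expected overlap at junction k: how many bases of fragment k+1 attend
  # before the end of fragment k's raw span
  exp_ov <- if (length(preds) > 1L) {
    vapply(seq_along(preds)[-1L], function(k)
      sum(positions[[k]] < spans[k - 1L, 2L]), 0)
  } else NULL
  merge_samples(preds, read_id = read_id, expected_overlap = exp_ov,
                overlap_slack = 3L)
}
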