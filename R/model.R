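# Twin-encoder attention sequence-to-sequence basecalling model.
#
# Architecture: two stacked bidirectional LSTM encoders (one over raw signal
# values, one over event feature vectors), whose per-step outputs are the
# concatenation of the forward and backward hidden states (dimension
# 2 x latent).  In joint mode the two encoders' output sequences are
# concatenated along the step axis.  A single-layer LSTM decoder emits one
# token per step; at every step a multiplicative (Luong) attention scores the
# decoder state against all unmasked encoder outputs,
#     score(h_dec, hbar_s) = h_dec' W_a hbar_s,
#     alpha = softmax(score)  over unmasked steps,
#     c     = sum_s alpha_s hbar_s,
# and the attentional vector htilde = tanh(W_c [c; h_dec]) is projected to
# 7 token logits.  htilde is also fed back as part of the next decoder input
# (input feeding).  Everything - forward pass, analytic backpropagation, Adam,
# gradient clipping, scheduled sampling - is implemented natively in R; the
# backward pass is validated against numerical differentiation in the tests.

#' Model configuration
#'
#' @param latent_dim LSTM hidden width for encoders and decoder (128 by
#'   default)
#' @param encoder_layers stacked BiLSTM layers per encoder (2 by default)
#' @param mode which inputs the model consumes: "raw", "event" or "joint"
#' @param rawmax,eventmax padded input lengths (encoder steps)
#' @param decode_max decoding length cap in tokens
#' @return list of class `model_config`
#' @export
model_config <- function(latent_dim = 128L, encoder_layers = 2L,
                         mode = c("joint", "raw", "event"),
                         rawmax = 200L, eventmax = 30L, decode_max = 40L) {
  mode <- match.arg(mode)
  stopifnot(latent_dim >= 1, encoder_layers >= 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 encoder_layers = as.integer(encoder_layers),
                 decoder_layers = 1L,
                 vocab_size = VOCAB_SIZE,
                 mode = mode,
                 rawmax = as.integer(rawmax),
                 eventmax = as.integer(eventmax),
                 decode_max = as.integer(decode_max)),
            class = "model_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise model parameters
#'
#' Glorot-uniform weights, zero biases with the LSTM forget-gate bias set to
#' 1 (a standard trick that eases early training).  Parameters live in a flat
#' named list so optimisation, clipping and gradient checking can treat them
#' uniformly.
#'
#' @param config a `model_config`
#' @param seed integer seed for the initial weights
#' @return object of class `squiggle_model`: list with `config` and `params`
#' @export
init_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  H <- config$latent_dim
  D <- 2L * H
  p <- list()
  lstm_par <- function(din) {
    W <- glorot(din + H, 4L * H)
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- 1  # forget gate bias
    list(W = W, b = b)
  }
  add_encoder <- function(p, name, din0) {
    din <- din0
    for (l in seq_len(config$encoder_layers)) {
      for (dir in c("fwd", "bwd")) {
        lp <- lstm_par(din)
        p[[sprintf("%s.l%d.%s.W", name, l, dir)]] <- lp$W
        p[[sprintf("%s.l%d.%s.b", name, l, dir)]] <- lp$b
      }
      din <- D
    }
    p
  }
  with_seed(seed, {
    if (config$mode %in% c("raw", "joint")) p <- add_encoder(p, "enc_raw", 1L)
    if (config$mode %in% c("event", "joint")) p <- add_encoder(p, "enc_evt", 5L)
    p$emb <- matrix(stats::rnorm(VOCAB_SIZE * H, 0, 0.1), VOCAB_SIZE, H)
    p$W_a <- glorot(H, D)
    dec <- lstm_par(2L * H)  # input: [token embedding; previous htilde]
    p$dec.W <- dec$W
    p$dec.b <- dec$b
    p$W_c <- glorot(D + H, H)
    p$b_c <- numeric(H)
    p$W_o <- glorot(H, VOCAB_SIZE)
    p$b_o <- numeric(VOCAB_SIZE)
  })
  structure(list(config = config, params = p), class = "squiggle_model")
}

#' @export
print.squiggle_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<squiggle_model> mode=%s latent=%d (%d parameters)\n",
              x$config$mode, x$config$latent_dim, np))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One LSTM step (decoder).  xh = cbind(input, h_prev).  Gate order i, f, g, o.
lstm_step <- function(xh, c_prev, W, b) {
  H <- ncol(W) / 4L
  B <- nrow(xh)
  z <- xh %*% W + rep(b, each = B)
  gs <- sigmoid(z[, c(seq_len(2L * H), 3L * H + seq_len(H)), drop = FALSE])
  i <- gs[, seq_len(H), drop = FALSE]
  f <- gs[, H + seq_len(H), drop = FALSE]
  o <- gs[, 2L * H + seq_len(H), drop = FALSE]
  g <- tanh(z[, 2L * H + seq_len(H), drop = FALSE])
  cc <- f * c_prev + i * g
  tc <- tanh(cc)
  list(h = o * tc, c = cc,
       cache = list(xh = xh, c_prev = c_prev, i = i, f = f, g = g, o = o,
                    tc = tc))
}

# The recurrent kernels exist twice: a compiled fast path (src/lstm.cpp) and
# a pure-R reference implementation; tests assert exact agreement.  Set
# options(squigglecall.use_cpp = FALSE) to force the reference path.
use_cpp <- function() isTRUE(getOption("squigglecall.use_cpp", TRUE))

# Run one LSTM direction over a flat step-major input Xflat ((S*B) x din;
# step s occupies rows (s-1)*B + 1..B).  The input projection and bias are
# applied to all steps in one matmul; only the hidden recurrence is stepwise.
lstm_dir_forward_flat <- function(Xflat, S, B, W, b, reverse = FALSE,
                                  keep_cache = FALSE) {
  if (use_cpp())
    return(.lstm_dir_forward_cpp(Xflat, S, B, W, b, reverse, keep_cache))
  lstm_dir_forward_flat_r(Xflat, S, B, W, b, reverse, keep_cache)
}

lstm_dir_forward_flat_r <- function(Xflat, S, B, W, b, reverse = FALSE,
                                    keep_cache = FALSE) {
  H <- ncol(W) / 4L
  din <- nrow(W) - H
  Wx <- W[seq_len(din), , drop = FALSE]
  Wh <- W[din + seq_len(H), , drop = FALSE]
  ZX <- Xflat %*% Wx + rep(b, each = S * B)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  Hout <- matrix(0, S * B, H)
  cache <- if (keep_cache) {
    z0 <- function() matrix(0, S * B, H)
    list(I = z0(), F = z0(), G = z0(), O = z0(), TC = z0(), CPREV = z0(),
         HPREV = z0())
  } else NULL
  i3 <- 2L * H + seq_len(H)
  sel <- c(seq_len(2L * H), 3L * H + seq_len(H))
  for (t in (if (reverse) S:1 else 1:S)) {
    rows <- (t - 1L) * B + seq_len(B)
    z <- ZX[rows, , drop = FALSE] + h %*% Wh
    gs <- sigmoid(z[, sel, drop = FALSE])
    i <- gs[, seq_len(H), drop = FALSE]
    f <- gs[, H + seq_len(H), drop = FALSE]
    o <- gs[, 2L * H + seq_len(H), drop = FALSE]
    g <- tanh(z[, i3, drop = FALSE])
    if (keep_cache) {
      cache$I[rows, ] <- i; cache$F[rows, ] <- f; cache$G[rows, ] <- g
      cache$O[rows, ] <- o; cache$CPREV[rows, ] <- cc; cache$HPREV[rows, ] <- h
    }
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    if (keep_cache) cache$TC[rows, ] <- tc
    Hout[rows, ] <- h
  }
  if (keep_cache) cache$Xflat <- Xflat
  list(h = Hout, cache = cache)
}

# Stacked BiLSTM encoder on flat step-major input; returns the top layer's
# flat output ((S*B) x 2H) and per-layer caches.
bilstm_forward <- function(params, name, layers, Xflat, S, B,
                           keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", layers) else NULL
  inp <- Xflat
  for (l in seq_len(layers)) {
    fw <- lstm_dir_forward_flat(inp, S, B,
                                params[[sprintf("%s.l%d.fwd.W", name, l)]],
                                params[[sprintf("%s.l%d.fwd.b", name, l)]],
                                reverse = FALSE, keep_cache = keep_cache)
    bw <- lstm_dir_forward_flat(inp, S, B,
                                params[[sprintf("%s.l%d.bwd.W", name, l)]],
                                params[[sprintf("%s.l%d.bwd.b", name, l)]],
                                reverse = TRUE, keep_cache = keep_cache)
    out <- cbind(fw$h, bw$h)
    if (keep_cache) cache[[l]] <- list(fwd = fw$cache, bwd = bw$cache)
    inp <- out
  }
  list(out = inp, cache = cache)
}

# flat step-major views of the batch inputs (column-major = batch fastest)
batch_raw_flat <- function(batch) matrix(as.vector(batch$raw), ncol = 1L)

batch_evt_flat <- function(batch) {
  d <- dim(batch$events)
  matrix(as.vector(batch$events), d[1L] * d[2L], 5L)
}

#' Encode a batch
#'
#' Runs the encoder(s) selected by the model's mode and flattens the per-step
#' outputs into the attention-ready layout.  In joint mode the raw steps come
#' first, then the event steps, and the masks are concatenated likewise.
#'
#' @param model a `squiggle_model`
#' @param batch a batch from [make_batches()]
#' @param keep_cache keep intermediate activations (needed for training)
#' @return object of class `encoder_outputs`: list with `Hflat`
#'   (`(B*S) x 2*latent`, step-major with batch fastest), `mask` (B x S),
#'   `B`, `S`, `S_raw`, `S_evt`, `D`
#' @export
encode <- function(model, batch, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  B <- batch$n
  outs <- list()
  masks <- list()
  cache <- list()
  S_raw <- 0L
  S_evt <- 0L
  if (cfg$mode %in% c("raw", "joint")) {
    S_raw <- ncol(batch$raw)
    er <- bilstm_forward(p, "enc_raw", cfg$encoder_layers,
                         batch_raw_flat(batch), S_raw, B, keep_cache)
    outs <- c(outs, list(er$out))
    masks <- c(masks, list(batch$raw_mask))
    if (keep_cache) cache$raw <- er$cache
  }
  if (cfg$mode %in% c("event", "joint")) {
    S_evt <- dim(batch$events)[2L]
    ee <- bilstm_forward(p, "enc_evt", cfg$encoder_layers,
                         batch_evt_flat(batch), S_evt, B, keep_cache)
    outs <- c(outs, list(ee$out))
    masks <- c(masks, list(batch$event_mask))
    if (keep_cache) cache$evt <- ee$cache
  }
  Hflat <- do.call(rbind, outs)
  mask <- do.call(cbind, masks)
  structure(list(Hflat = Hflat, mask = mask, B = B, S = S_raw + S_evt,
                 S_raw = S_raw, S_evt = S_evt, D = 2L * cfg$latent_dim,
                 cache = if (keep_cache) cache else NULL),
            class = "encoder_outputs")
}

# einsum 'bsd,bd->bs' on the flat (B*S) x D layout
flat_dot <- function(Hflat, v, B, S) {
  if (use_cpp()) return(.flat_dot_cpp(Hflat, v, B, S))
  acc <- numeric(B * S)
  for (d in seq_len(ncol(Hflat))) acc <- acc + Hflat[, d] * v[, d]
  matrix(acc, B, S)
}

# weighted sum over the step axis: out[b,] = sum_s w[(s-1)B+b] * M[(s-1)B+b,]
flat_contract <- function(M, w, B, S) {
  if (use_cpp()) return(.flat_contract_cpp(M, w, B, S))
  M <- M * w
  D <- ncol(M)
  dim(M) <- c(B, S, D)
  colSums(aperm(M, c(2L, 1L, 3L)))
}

# accumulate M[(s-1)B+b,] + w[(s-1)B+b] * v[b,]; the compiled path mutates
# M in place (callers pass a fresh private matrix)
flat_scatter_add <- function(M, w, v, B, S) {
  if (use_cpp()) {
    .flat_scatter_add_cpp(M, w, v, B, S)
    return(M)
  }
  for (d in seq_len(ncol(M))) M[, d] <- M[, d] + w * v[, d]
  M
}

#' Multiplicative attention
#'
#' Scores the decoder state against every encoder output,
#' `score_s = h_dec' W_a hbar_s`, softmax-normalises over unmasked steps and
#' returns the attention weights and the context vector
#' `c = sum_s alpha_s hbar_s`.  Weights on masked (padding) steps are exactly
#' zero.
#'
#' @param h_dec decoder hidden state (B x latent)
#' @param enc an `encoder_outputs`
#' @param W_a attention weight matrix (latent x 2*latent)
#' @return list with `alpha` (B x S), `context` (B x 2*latent), `q`
#' @export
attend <- function(h_dec, enc, W_a) {
  B <- enc$B; S <- enc$S
  if (any(rowSums(enc$mask) == 0)) stop("all encoder steps masked for a sample")
  q <- h_dec %*% W_a
  sc <- flat_dot(enc$Hflat, q, B, S)
  sc[enc$mask == 0] <- -Inf
  mx <- sc[cbind(seq_len(B), max.col(sc, ties.method = "first"))]
  ex <- exp(sc - mx)
  alpha <- ex / rowSums(ex)
  ctx <- flat_contract(enc$Hflat, as.vector(alpha), B, S)
  list(alpha = alpha, context = ctx, q = q)
}

#' One decoder step
#'
#' Embeds the previous token, concatenates the previous attentional vector
#' (input feeding), advances the decoder LSTM, attends over the encoder
#' outputs and produces 7 token logits.
#'
#' @param model a `squiggle_model`
#' @param prev_tokens integer vector (length B) of previous token ids
#' @param state decoder state as returned by [decoder_init()] or a previous
#'   call (list `h`, `c`, `htilde`)
#' @param enc an `encoder_outputs`
#' @param keep_cache keep activations for backpropagation
#' @return list with `logits` (B x 7), `state`, `alpha`, and `cache`
#' @export
decode_step <- function(model, prev_tokens, state, enc, keep_cache = FALSE) {
  p <- model$params
  if (any(prev_tokens < 0L | prev_tokens >= VOCAB_SIZE))
    stop("invalid token id")
  B <- length(prev_tokens)
  emb <- p$emb[prev_tokens + 1L, , drop = FALSE]
  xh <- cbind(emb, state$htilde, state$h)
  st <- lstm_step(xh, state$c, p$dec.W, p$dec.b)
  att <- attend(st$h, enc, p$W_a)
  comb <- cbind(att$context, st$h)
  pre <- comb %*% p$W_c + rep(p$b_c, each = B)
  htilde <- tanh(pre)
  logits <- htilde %*% p$W_o + rep(p$b_o, each = B)
  cache <- if (keep_cache) {
    list(lstm = st$cache, att = att, comb = comb, htilde = htilde,
         prev_tokens = prev_tokens, h_dec = st$h)
  } else NULL
  list(logits = logits,
       state = list(h = st$h, c = st$c, htilde = htilde),
       alpha = att$alpha, cache = cache)
}

#' Initial decoder state (all zeros)
#' @param model a `squiggle_model`
#' @param B batch size
#' @export
decoder_init <- function(model, B) {
  H <- model$config$latent_dim
  list(h = matrix(0, B, H), c = matrix(0, B, H), htilde = matrix(0, B, H))
}

log_softmax <- function(logits) {
  mx <- logits[cbind(seq_len(nrow(logits)),
                     max.col(logits, ties.method = "first"))]
  z <- logits - mx
  z - log(rowSums(exp(z)))
}

#' Masked sequence cross-entropy loss
#'
#' Mean over unmasked target positions of the per-token cross-entropy.
#' Padding positions (mask 0) contribute nothing.
#'
#' @param logits_list list over decode steps of (B x 7) logit matrices; step t
#'   predicts target column t+1
#' @param target integer matrix (B x T) of token ids, starting with START
#' @param target_mask 0/1 matrix marking real (non-padding) tokens
#' @return scalar loss (natural log units)
#' @export
sequence_loss <- function(logits_list, target, target_mask) {
  total <- 0
  wsum <- 0
  B <- nrow(target)
  for (t in seq_along(logits_list)) {
    w <- target_mask[, t + 1L]
    if (!any(w > 0)) next
    lp <- log_softmax(logits_list[[t]])
    picked <- lp[cbind(seq_len(B), target[, t + 1L] + 1L)]
    total <- total - sum(w * picked)
    wsum <- wsum + sum(w)
  }
  if (wsum == 0) stop("empty target mask")
  total / wsum
}
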