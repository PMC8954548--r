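# Analytic backpropagation, Adam, gradient clipping and the training loop.
#
# The backward pass mirrors model.R step by step; it is checked against
# numerical differentiation in the test suite.  Scheduled sampling: at each
# decoder time step, each sample independently receives either the
# ground-truth previous token (probability `sampling_ratio`) or the model's
# own argmax prediction; gradients do not flow through the sampled token
# (standard stop-gradient treatment).

#' Training configuration
#'
#' @param epochs training epochs
#' @param batch_size samples per batch
#' @param lr Adam learning rate
#' @param clip_norm global L2 gradient-norm bound (gradients are rescaled so
#'   their joint norm never exceeds this)
#' @param sampling_ratio scheduled-sampling probability of feeding the
#'   ground-truth previous token (1 = pure teacher forcing).  With the
#'   default "linear" schedule this is the *final* ratio: training starts at
#'   pure teacher forcing and decays linearly to `sampling_ratio` by the last
#'   epoch (the classic scheduled-sampling curriculum); "constant" holds the
#'   ratio fixed from the first epoch
#' @param schedule "linear" (decay 1 -> sampling_ratio over the epochs) or
#'   "constant"
#' @param seed integer seed for shuffling and sampling draws
#' @param verbose print per-epoch losses
#' @return list of class `train_config`
#' @export
train_config <- function(epochs = 10L, batch_size = 128L, lr = 1e-3,
                         clip_norm = 1.0, sampling_ratio = 0.5,
                         schedule = c("linear", "constant"), seed = 1L,
                         verbose = FALSE) {
  schedule <- match.arg(schedule)
  stopifnot(clip_norm > 0, sampling_ratio >= 0, sampling_ratio <= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 clip_norm = clip_norm, sampling_ratio = sampling_ratio,
                 schedule = schedule,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

# teacher-forcing probability for epoch ep of n under the config's schedule
epoch_ratio <- function(tc, ep, n) {
  if (identical(tc$schedule, "constant") || n <= 1L) return(tc$sampling_ratio)
  1 - (1 - tc$sampling_ratio) * (ep - 1) / (n - 1)
}

# -- backward pass ------------------------------------------------------------

# Backward through one LSTM direction on the flat layout.  dH: (S*B) x H
# gradient w.r.t. the direction's hidden outputs.  The per-step loop handles
# only the recurrence; weight/input gradients are batched matmuls.
lstm_dir_backward <- function(dH, cache, W, S, B, reverse = FALSE) {
  if (use_cpp()) return(.lstm_dir_backward_cpp(dH, cache, W, S, B, reverse))
  lstm_dir_backward_r(dH, cache, W, S, B, reverse)
}

lstm_dir_backward_r <- function(dH, cache, W, S, B, reverse = FALSE) {
  H <- ncol(W) / 4L
  din <- nrow(W) - H
  Wx <- W[seq_len(din), , drop = FALSE]
  Wh <- W[din + seq_len(H), , drop = FALSE]
  tWh <- t(Wh)
  dZ <- matrix(0, S * B, 4L * H)
  dh_carry <- matrix(0, B, H)
  dc_carry <- matrix(0, B, H)
  for (t in (if (reverse) 1:S else S:1)) {  # reverse temporal order
    rows <- (t - 1L) * B + seq_len(B)
    i <- cache$I[rows, , drop = FALSE]
    f <- cache$F[rows, , drop = FALSE]
    g <- cache$G[rows, , drop = FALSE]
    o <- cache$O[rows, , drop = FALSE]
    tc <- cache$TC[rows, , drop = FALSE]
    dh <- dH[rows, , drop = FALSE] + dh_carry
    dcv <- dc_carry + dh * o * (1 - tc^2)
    dz <- cbind((dcv * g) * i * (1 - i),
                (dcv * cache$CPREV[rows, , drop = FALSE]) * f * (1 - f),
                (dcv * i) * (1 - g^2),
                (dh * tc) * o * (1 - o))
    dZ[rows, ] <- dz
    dh_carry <- dz %*% tWh
    dc_carry <- dcv * f
  }
  list(dW = rbind(crossprod(cache$Xflat, dZ), crossprod(cache$HPREV, dZ)),
       db = colSums(dZ),
       dX = tcrossprod(dZ, Wx))
}

# Backward through a stacked BiLSTM encoder.  dOut: (S*B) x 2H gradient
# w.r.t. the top-layer concatenated outputs.
bilstm_backward <- function(params, name, layers, dOut, cache, gr, S, B) {
  H <- ncol(dOut) / 2L
  for (l in layers:1L) {
    Wf <- params[[sprintf("%s.l%d.fwd.W", name, l)]]
    Wb <- params[[sprintf("%s.l%d.bwd.W", name, l)]]
    bf <- lstm_dir_backward(dOut[, seq_len(H), drop = FALSE],
                            cache[[l]]$fwd, Wf, S, B, reverse = FALSE)
    bb <- lstm_dir_backward(dOut[, H + seq_len(H), drop = FALSE],
                            cache[[l]]$bwd, Wb, S, B, reverse = TRUE)
    gr[[sprintf("%s.l%d.fwd.W", name, l)]] <-
      gr[[sprintf("%s.l%d.fwd.W", name, l)]] + bf$dW
    gr[[sprintf("%s.l%d.fwd.b", name, l)]] <-
      gr[[sprintf("%s.l%d.fwd.b", name, l)]] + bf$db
    gr[[sprintf("%s.l%d.bwd.W", name, l)]] <-
      gr[[sprintf("%s.l%d.bwd.W", name, l)]] + bb$dW
    gr[[sprintf("%s.l%d.bwd.b", name, l)]] <-
      gr[[sprintf("%s.l%d.bwd.b", name, l)]] + bb$db
    if (l > 1L) dOut <- bf$dX + bb$dX
  }
  gr
}

zero_grads <- function(params) {
  lapply(params, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
         else numeric(length(p)))
}

#' Forward and backward pass on one batch
#'
#' Runs the full teacher-forced / scheduled-sampling decode, computes the
#' masked cross-entropy loss and the analytic gradient of every parameter.
#' Scheduled-sampling draws use the current RNG state.
#'
#' @param model a `squiggle_model`
#' @param batch a target-carrying batch
#' @param sampling_ratio probability of feeding ground truth at each step
#' @return list with `loss` and `grads` (flat list matching `model$params`)
#' @export
forward_backward <- function(model, batch, sampling_ratio = 1) {
  cfg <- model$config
  p <- model$params
  B <- batch$n
  H <- cfg$latent_dim
  enc <- encode(model, batch, keep_cache = TRUE)
  S <- enc$S
  D <- enc$D
  target <- batch$target
  tmask <- batch$target_mask
  steps <- ncol(target) - 1L
  state <- decoder_init(model, B)
  caches <- vector("list", steps)
  logits_list <- vector("list", steps)
  prev <- target[, 1L]
  prev_list <- vector("list", steps)
  for (t in seq_len(steps)) {
    prev_list[[t]] <- prev
    ds <- decode_step(model, prev, state, enc, keep_cache = TRUE)
    caches[[t]] <- ds$cache
    logits_list[[t]] <- ds$logits
    state <- ds$state
    if (t < steps) {
      use_truth <- stats::runif(B) < sampling_ratio
      pred <- max.col(ds$logits, ties.method = "first") - 1L
      prev <- ifelse(use_truth, target[, t + 1L], pred)
    }
  }
  wsum <- sum(tmask[, -1L, drop = FALSE][, seq_len(steps), drop = FALSE])
  if (wsum == 0) stop("empty target mask")
  loss <- 0
  gr <- zero_grads(p)
  dHflat <- matrix(0, B * S, D)
  dh_carry <- matrix(0, B, H)
  dc_carry <- matrix(0, B, H)
  dhtilde_carry <- matrix(0, B, H)
  grp <- rep.int(seq_len(B), S)
  for (t in steps:1L) {
    cc <- caches[[t]]
    w <- tmask[, t + 1L]
    lp <- log_softmax(logits_list[[t]])
    lab <- target[, t + 1L] + 1L
    loss <- loss - sum(w * lp[cbind(seq_len(B), lab)])
    P <- exp(lp)
    dlog <- P * (w / wsum)
    dlog[cbind(seq_len(B), lab)] <- dlog[cbind(seq_len(B), lab)] - w / wsum
    gr$W_o <- gr$W_o + crossprod(cc$htilde, dlog)
    gr$b_o <- gr$b_o + colSums(dlog)
    dhtilde <- tcrossprod(dlog, p$W_o) + dhtilde_carry
    dpre <- dhtilde * (1 - cc$htilde^2)
    gr$W_c <- gr$W_c + crossprod(cc$comb, dpre)
    gr$b_c <- gr$b_c + colSums(dpre)
    dcomb <- tcrossprod(dpre, p$W_c)
    dctx <- dcomb[, seq_len(D), drop = FALSE]
    dh_dec <- dcomb[, D + seq_len(H), drop = FALSE] + dh_carry
    # attention backward
    alpha <- cc$att$alpha
    avec <- as.vector(alpha)
    q <- cc$att$q
    dalpha <- flat_dot(enc$Hflat, dctx, B, S)
    dHflat <- flat_scatter_add(dHflat, avec, dctx, B, S)
    dscore <- alpha * (dalpha - rowSums(alpha * dalpha))
    dsvec <- as.vector(dscore)
    dq <- flat_contract(enc$Hflat, dsvec, B, S)
    dHflat <- flat_scatter_add(dHflat, dsvec, q, B, S)
    gr$W_a <- gr$W_a + crossprod(cc$h_dec, dq)
    dh_dec <- dh_dec + tcrossprod(dq, p$W_a)
    # decoder LSTM single-step backward
    lc <- cc$lstm
    dcv <- dc_carry + dh_dec * lc$o * (1 - lc$tc^2)
    do_ <- dh_dec * lc$tc
    dz <- cbind((dcv * lc$g) * lc$i * (1 - lc$i),
                (dcv * lc$c_prev) * lc$f * (1 - lc$f),
                (dcv * lc$i) * (1 - lc$g^2),
                do_ * lc$o * (1 - lc$o))
    gr$dec.W <- gr$dec.W + crossprod(lc$xh, dz)
    gr$dec.b <- gr$dec.b + colSums(dz)
    dxh <- tcrossprod(dz, p$dec.W)
    demb <- dxh[, seq_len(H), drop = FALSE]
    dhtilde_carry <- dxh[, H + seq_len(H), drop = FALSE]
    dh_carry <- dxh[, 2L * H + seq_len(H), drop = FALSE]
    dc_carry <- dcv * lc$f
    rs <- rowsum(demb, group = prev_list[[t]], reorder = TRUE)
    rows <- as.integer(rownames(rs)) + 1L
    gr$emb[rows, ] <- gr$emb[rows, ] + rs
  }
  loss <- loss / wsum
  if (!is.finite(loss)) stop("non-finite loss; aborting (check inputs/lr)")
  # encoder backward (raw block rows first, then event block)
  if (cfg$mode %in% c("raw", "joint")) {
    gr <- bilstm_backward(p, "enc_raw", cfg$encoder_layers,
                          dHflat[seq_len(enc$S_raw * B), , drop = FALSE],
                          enc$cache$raw, gr, enc$S_raw, B)
  }
  if (cfg$mode %in% c("event", "joint")) {
    gr <- bilstm_backward(p, "enc_evt", cfg$encoder_layers,
                          dHflat[enc$S_raw * B + seq_len(enc$S_evt * B),
                                 , drop = FALSE],
                          enc$cache$evt, gr, enc$S_evt, B)
  }
  list(loss = loss, grads = gr)
}

#' Clip gradients to a global L2 norm
#'
#' @param grads flat gradient list
#' @param clip_norm maximum joint L2 norm
#' @return list with rescaled `grads` and the pre-clip `norm`
#' @export
clip_global_norm <- function(grads, clip_norm) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(nrm) && nrm > clip_norm) {
    scale <- clip_norm / nrm
    grads <- lapply(grads, function(g) g * scale)
  }
  list(grads = grads, norm = nrm)
}

adam_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

adam_update <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

#' One optimisation step on one batch
#'
#' Forward/backward with scheduled sampling, global-norm gradient clipping,
#' Adam update.
#'
#' @param model a `squiggle_model`
#' @param batch a batch with targets
#' @param tc a `train_config`
#' @param opt Adam state from [adam_init()] (created if NULL)
#' @return list with updated `model`, `opt`, `loss`, `grad_norm`
#' @export
train_step <- function(model, batch, tc = train_config(), opt = NULL,
                       ratio = tc$sampling_ratio) {
  if (is.null(opt)) opt <- adam_init(model$params)
  fb <- forward_backward(model, batch, ratio)
  cl <- clip_global_norm(fb$grads, tc$clip_norm)
  up <- adam_update(model$params, cl$grads, opt, lr = tc$lr)
  model$params <- up$params
  list(model = model, opt = up$opt, loss = fb$loss, grad_norm = cl$norm)
}

#' Teacher-forced loss of a sample set (no gradients)
#'
#' @param model a `squiggle_model`
#' @param samples scaled, tokenized samples
#' @param batch_size batch size
#' @param target_len target padding length
#' @return mean of per-batch losses
#' @export
evaluate_loss <- function(model, samples, batch_size = 128L,
                          target_len = NULL) {
  batches <- make_batches(samples, batch_size, model$config$rawmax,
                          model$config$eventmax, target_len = target_len)
  losses <- vapply(batches, function(b) {
    enc <- encode(model, b)
    steps <- ncol(b$target) - 1L
    state <- decoder_init(model, b$n)
    logits <- vector("list", steps)
    for (t in seq_len(steps)) {
      ds <- decode_step(model, b$target[, t], state, enc)
      logits[[t]] <- ds$logits
      state <- ds$state
    }
    sequence_loss(logits, b$target, b$target_mask)
  }, 0)
  mean(losses)
}

#' Train a model on prepared samples
#'
#' Shuffles the training samples each epoch (seeded), batches them and runs
#' [train_step()] on every batch; training and validation losses are logged
#' after each epoch.
#'
#' @param model a `squiggle_model`
#' @param train_samples,val_samples scaled, tokenized sample lists
#' @param tc a `train_config`
#' @param target_len target padding length (longest training target if NULL)
#' @return list with `model`, `log` (data.frame epoch/train_loss/val_loss),
#'   `target_len`
#' @export
train_model <- function(model, train_samples, val_samples = NULL,
                        tc = train_config(), target_len = NULL) {
  if (is.null(target_len))
    target_len <- max(vapply(train_samples, function(s) length(s$tokens), 1L))
  opt <- adam_init(model$params)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample.int(length(train_samples))
      batches <- make_batches(train_samples[ord], tc$batch_size,
                              model$config$rawmax, model$config$eventmax,
                              target_len = target_len)
      ep_loss <- 0
      ratio <- epoch_ratio(tc, ep, tc$epochs)
      for (b in batches) {
        st <- train_step(model, b, tc, opt, ratio = ratio)
        model <- st$model
        opt <- st$opt
        ep_loss <- ep_loss + st$loss * b$n
      }
      ep_loss <- ep_loss / length(train_samples)
      vl <- if (length(val_samples))
        evaluate_loss(model, val_samples, tc$batch_size, target_len) else NA
      log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_loss = vl))
      if (tc$verbose)
        message(sprintf("epoch %d: train %.4f val %s", ep, ep_loss,
                        ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
    }
  })
  list(model = model, log = log, target_len = target_len)
}
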