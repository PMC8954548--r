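make_batch_for <- function(model, n = 3L, seed = 21L) {
  cfg <- model$config
  ss <- lapply(seq_len(n), function(i)
    toy_sample(raw_len = cfg$rawmax - (i - 1L) * 5L,
               event_count = max(1L, cfg$eventmax - i + 1L),
               bases = random_bases(3L + i, seed + i), seed = seed + 10L * i))
  make_batches(ss, 64L, cfg$rawmax, cfg$eventmax)[[1L]]
}

test_that("encoder output geometry follows the mode", {
  m <- tiny_model(mode = "joint", latent = 5L, rawmax = 12L, eventmax = 4L)
  b <- make_batch_for(m)
  enc <- encode(m, b)
  expect_identical(enc$S, 16L)           # rawmax + eventmax
  expect_identical(ncol(enc$Hflat), 10L) # 2 x latent
  expect_identical(nrow(enc$Hflat), enc$S * b$n)
  expect_identical(dim(enc$mask), c(b$n, 16L))
  # default geometry: joint attention axis is 200 + 30 = 230 wide
  cfg <- model_config(latent_dim = 128L, mode = "joint")
  expect_identical(cfg$rawmax + cfg$eventmax, 230L)
  # raw mode ignores the event block entirely
  mr <- tiny_model(mode = "raw", latent = 5L, rawmax = 12L, eventmax = 4L)
  e1 <- encode(mr, b)
  b2 <- b
  b2$events <- b2$events + 100
  e2 <- encode(mr, b2)
  expect_identical(e1$Hflat, e2$Hflat)
  expect_identical(e1$S, 12L)
})

test_that("attention weights are normalised and exactly masked", {
  m <- tiny_model(latent = 5L, rawmax = 12L, eventmax = 4L)
  b <- make_batch_for(m)
  enc <- encode(m, b)
  h_dec <- matrix(squigglecall:::with_seed(3, stats::rnorm(b$n * 5)), b$n, 5)
  at <- attend(h_dec, enc, m$params$W_a)
  expect_equal(rowSums(at$alpha), rep(1, b$n))
  expect_true(all(at$alpha[enc$mask == 0] == 0))
  # uniform scores -> uniform weights over unmasked steps
  enc0 <- enc
  enc0$Hflat <- matrix(0, nrow(enc$Hflat), ncol(enc$Hflat))
  at0 <- attend(h_dec, enc0, m$params$W_a)
  for (i in seq_len(b$n)) {
    k <- sum(enc$mask[i, ])
    expect_equal(unname(at0$alpha[i, enc$mask[i, ] == 1]), rep(1 / k, k))
  }
  # single unmasked step -> weight 1 there and context = that output
  enc1 <- enc
  enc1$mask <- matrix(0, b$n, enc$S)
  enc1$mask[, 3L] <- 1
  at1 <- attend(h_dec, enc1, m$params$W_a)
  expect_equal(unname(at1$alpha[, 3L]), rep(1, b$n))
  expect_equal(at1$context, enc$Hflat[2L * b$n + seq_len(b$n), ],
               ignore_attr = TRUE)
  # fully masked input is an error
  encx <- enc
  encx$mask[1L, ] <- 0
  expect_error(attend(h_dec, encx, m$params$W_a), "masked")
})

test_that("decode_step produces valid, deterministic 7-token logits", {
  m <- tiny_model(latent = 6L, rawmax = 12L, eventmax = 4L)
  b <- make_batch_for(m)
  enc <- encode(m, b)
  st <- decoder_init(m, b$n)
  ds <- decode_step(m, rep(1L, b$n), st, enc)
  expect_identical(dim(ds$logits), c(b$n, 7L))
  p <- exp(squigglecall:::log_softmax(ds$logits))
  expect_equal(rowSums(p), rep(1, b$n))
  ds2 <- decode_step(m, rep(1L, b$n), st, enc)
  expect_identical(ds$logits, ds2$logits)
  expect_equal(rowSums(ds$alpha), rep(1, b$n))
  expect_error(decode_step(m, rep(9L, b$n), st, enc), "invalid token")
})

test_that("masked cross-entropy loss behaves per definition", {
  # uniform predictions over 7 tokens -> ln 7
  tgt <- matrix(c(1L, 3L, 4L, 2L), 1L, 4L)
  msk <- matrix(1, 1L, 4L)
  logits <- lapply(1:3, function(i) matrix(0, 1L, 7L))
  expect_equal(sequence_loss(logits, tgt, msk), log(7))
  # one-hot correct predictions -> ~0
  big <- lapply(2:4, function(j) {
    l <- matrix(-1e6, 1L, 7L); l[1L, tgt[1, j] + 1L] <- 0; l
  })
  expect_equal(sequence_loss(big, tgt, msk), 0, tolerance = 1e-9)
  # padding positions contribute nothing
  tgt2 <- rbind(tgt, c(1L, 5L, 2L, 0L))
  msk2 <- rbind(msk, c(1, 1, 1, 0))
  l1 <- lapply(1:3, function(i)
    matrix(squigglecall:::with_seed(i, stats::rnorm(14)), 2L, 7L))
  base <- sequence_loss(l1, tgt2, msk2)
  l1b <- l1
  l1b[[3L]][2L, ] <- 99  # only a padded position of sample 2 changes
  expect_equal(sequence_loss(l1b, tgt2, msk2), base)
  expect_error(sequence_loss(l1, tgt2, matrix(0, 2L, 4L)), "empty target mask")
})

test_that("analytic gradients match numerical differentiation", {
  m <- tiny_model(mode = "joint", latent = 4L, rawmax = 8L, eventmax = 3L)
  b <- make_batch_for(m, n = 2L, seed = 5L)
  fb <- forward_backward(m, b, sampling_ratio = 1)
  loss_at <- function(mm) forward_backward(mm, b, sampling_ratio = 1)$loss
  eps <- 1e-6
  check <- c("enc_raw.l1.fwd.W", "enc_raw.l2.bwd.W", "enc_raw.l1.bwd.b",
             "enc_evt.l1.fwd.W", "enc_evt.l2.fwd.b", "emb", "W_a",
             "dec.W", "dec.b", "W_c", "b_c", "W_o", "b_o")
  for (nm in check) {
    p <- m$params[[nm]]
    idx <- squigglecall:::with_seed(nchar(nm),
                                    sample(length(p), min(3L, length(p))))
    for (i in idx) {
      mp <- m; mp$params[[nm]][i] <- p[i] + eps
      mm2 <- m; mm2$params[[nm]][i] <- p[i] - eps
      num <- (loss_at(mp) - loss_at(mm2)) / (2 * eps)
      expect_equal(fb$grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("compiled kernels agree exactly with the R reference path", {
  m <- tiny_model(mode = "joint", latent = 5L, rawmax = 10L, eventmax = 4L)
  b <- make_batch_for(m, n = 3L, seed = 8L)
  run_both <- function(expr) {
    old <- options(squigglecall.use_cpp = TRUE)
    on.exit(options(old))
    a <- squigglecall:::with_seed(17, expr())
    options(squigglecall.use_cpp = FALSE)
    r <- squigglecall:::with_seed(17, expr())
    list(cpp = a, ref = r)
  }
  fb <- run_both(function() forward_backward(m, b, sampling_ratio = 0.5))
  expect_equal(fb$cpp$loss, fb$ref$loss, tolerance = 1e-12)
  for (nm in names(fb$cpp$grads))
    expect_equal(fb$cpp$grads[[nm]], fb$ref$grads[[nm]], tolerance = 1e-9,
                 ignore_attr = TRUE, label = nm)
  ge <- run_both(function() {
    enc <- encode(m, b)
    greedy_decode(m, enc)
  })
  expect_identical(lapply(ge$cpp, `[[`, "tokens"),
                   lapply(ge$ref, `[[`, "tokens"))
})

test_that("gradient clipping bounds the global norm", {
  m <- tiny_model(latent = 4L, rawmax = 8L, eventmax = 3L)
  b <- make_batch_for(m, n = 2L)
  fb <- forward_backward(m, b, 1)
  big <- lapply(fb$grads, function(g) g * 1e4)
  cl <- clip_global_norm(big, 1.0)
  expect_gt(cl$norm, 1)
  post <- sqrt(sum(vapply(cl$grads, function(g) sum(g^2), 0)))
  expect_lte(post, 1 + 1e-8)
  # norms already inside the bound are untouched
  small <- lapply(fb$grads, function(g) g * 1e-6)
  cl2 <- clip_global_norm(small, 1.0)
  expect_identical(cl2$grads, small)
})

test_that("training memorises a small toy set (overfit sanity)", {
  ss <- toy_sample_set(10, seed = 2)
  m <- tiny_model(mode = "joint", latent = 16L, rawmax = 40L, eventmax = 6L,
                  seed = 3L)
  tc <- train_config(epochs = 60L, batch_size = 10L, lr = 1e-2,
                     sampling_ratio = 1, seed = 4L)
  fit <- train_model(m, ss, tc = tc)
  expect_lt(utils::tail(fit$log$train_loss, 1), fit$log$train_loss[1L])
  expect_lt(utils::tail(fit$log$train_loss, 1), 0.5)
  # pure teacher forcing on a fixed batch with small lr: loss trends down
  tc2 <- train_config(epochs = 15L, batch_size = 10L, lr = 1e-3,
                      sampling_ratio = 1, seed = 5L)
  fit2 <- train_model(m, ss, tc = tc2)
  expect_lt(mean(utils::tail(fit2$log$train_loss, 3)),
            mean(utils::head(fit2$log$train_loss, 3)))
  # scheduled sampling extremes run (ratio 1 = pure teacher forcing)
  b <- make_batches(ss, 10L, 40L, 6L)[[1L]]
  st <- train_step(m, b, train_config(sampling_ratio = 1, seed = 1))
  expect_true(is.finite(st$loss))
})

test_that("full pipeline recovery: joint model >= 99% subset accuracy on an idealised corpus", {
  # memorisation-capacity sanity: noiseless, well-separated pore model with
  # constant dwell (so event boundaries align with bases and sample targets
  # are unambiguous); scaled-down window geometry (rawmax 96 / eventmax 16)
  params <- event_params()
  seed <- 5L
  basis <- generate_kmer_basis(3, seed = seed)
  pm <- pore_model(seed = seed, noise_sd = 0, dwell = "constant")
  ref <- generate_reference(basis, 1440, seed = seed + 1L)
  reads <- lapply(1:12, function(i) simulate_signal(
    substr(ref$sequence, (i - 1L) * 120L + 1L, i * 120L), pm,
    seed = seed + 1L + 10L * i, read_id = sprintf("r%02d", i)))
  samples <- list()
  for (r in reads) {
    ev <- detect_events(r$signal, params)
    samples <- c(samples, suppressWarnings(
      build_samples(r, ev, 96L, 16L, 1L)))
  }
  samples <- samples[vapply(samples, function(s) length(s$tokens) > 2L,
                            logical(1L))]
  sp <- split_dataset(samples, c(0.2, 0, 0.8), seed = 9L)
  sc <- fit_scalers(sp$train)
  trs <- apply_scalers(sp$train, sc)
  tes <- apply_scalers(sp$test, sc)
  tl <- max(vapply(trs, function(s) length(s$tokens), 1L)) + 2L
  m <- init_model(model_config(latent_dim = 24L, mode = "joint",
                               rawmax = 96L, eventmax = 16L,
                               decode_max = 24L), seed = 7L)
  tc <- train_config(epochs = 70L, batch_size = 64L, lr = 1e-2,
                     sampling_ratio = 0.5, seed = 42L)
  fit <- train_model(m, trs, tc = tc, target_len = tl)
  accs <- c()
  for (b in make_batches(tes, 64L, 96L, 16L, target_len = tl)) {
    dec <- greedy_decode(fit$model, encode(fit$model, b))
    for (i in seq_len(b$n))
      accs <- c(accs, subset_accuracy(
        detokenize(dec[[i]]$tokens),
        detokenize(b$target[i, b$target_mask[i, ] == 1])))
  }
  cat(sprintf("\n[recovery] held-out subset accuracy: %.4f (n=%d)\n",
              mean(accs), length(accs)))
  expect_gte(mean(accs), 0.99)
})
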