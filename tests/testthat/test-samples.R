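fake_events <- function(lengths) {
  starts <- cumsum(c(0L, lengths[-length(lengths)]))
  structure(data.frame(raw_start = starts, raw_length = lengths,
                       mean = seq_along(lengths), stdv = 0,
                       length = lengths, delta_mean = 0,
                       mean_sq = seq_along(lengths)^2),
            class = c("event_table", "data.frame"))
}

test_that("tokenizer vocabulary and round trip", {
  tok <- tokenizer()
  expect_length(tok, 7L)
  expect_identical(as.integer(tok), 0:6)
  expect_identical(tokenize("ACGT"), c(1L, 3L, 4L, 5L, 6L, 2L))
  for (seed in 1:5) {
    s <- random_bases(1 + seed * 3, seed)
    expect_identical(detokenize(tokenize(s)), s)
  }
  expect_identical(detokenize(tokenize("")), "")
  expect_error(tokenize("ACGN"), "unknown symbol")
  expect_error(detokenize(c(1L, 9L)), "invalid token")
})

test_that("sample building follows the greedy rawmax rule", {
  ev <- fake_events(c(50L, 60L, 70L, 30L, 40L))
  read <- list(signal = stats::runif(250), truth_ranges = NULL)
  ss <- build_samples(read, ev, rawmax = 200L, eventmax = 30L,
                      eventoffset = 1L)
  # sample 0: events 1..3 (180 raw; adding the 4th would reach 210)
  expect_identical(ss[[1L]]$event_count, 3L)
  expect_identical(ss[[1L]]$raw_len, 180L)
  # sample 1: events 2..5 (60+70+30+40 = 200)
  expect_identical(ss[[2L]]$event_count, 4L)
  expect_identical(ss[[2L]]$raw_len, 200L)
  # stride = number of events -> one sample per read
  ss2 <- build_samples(read, ev, 200L, 30L, eventoffset = nrow(ev))
  expect_length(ss2, 1L)
  # consecutive samples share events when the stride is small (overlap)
  expect_identical(ss[[1L]]$start_event + 1L, ss[[2L]]$start_event)
})

test_that("targets are the bases fully contained in the raw span", {
  ev <- fake_events(c(10L, 10L))
  truth <- data.frame(base_index = 0:2, base = c("A", "C", "G"),
                      raw_start = c(0L, 8L, 17L), raw_end = c(8L, 17L, 20L))
  read <- list(signal = stats::runif(20), truth_ranges = truth)
  # first sample spans [0, 20): all three bases
  ss <- build_samples(read, ev, rawmax = 20L, eventmax = 5L, eventoffset = 1L)
  expect_identical(ss[[1L]]$bases, "ACG")
  # restrict rawmax so the span is [0, 10): only base A ([0,8)) is contained
  ss2 <- build_samples(read, ev, rawmax = 10L, eventmax = 5L, eventoffset = 1L)
  expect_identical(ss2[[1L]]$bases, "A")
  expect_identical(ss2[[1L]]$tokens, c(1L, 3L, 2L))
})

test_that("oversized start events are skipped with a warning", {
  ev <- fake_events(c(300L, 10L))
  read <- list(signal = stats::runif(310), truth_ranges = NULL)
  expect_warning(ss <- build_samples(read, ev, rawmax = 200L, eventmax = 30L,
                                     eventoffset = 1L), "skipped")
  expect_length(ss, 1L)  # only the sample starting at event 2 survives
})

test_that("dataset splitting is seeded, disjoint and exhaustive", {
  ss <- toy_sample_set(40, seed = 3)
  sp <- split_dataset(ss, c(0.15, 0.15, 0.70), seed = 9)
  expect_identical(length(sp$test) + length(sp$validation) +
                     length(sp$train), 40L)
  ids <- function(x) vapply(x, function(s) paste(s$tokens, collapse = ","), "")
  all_ids <- c(ids(sp$test), ids(sp$validation), ids(sp$train))
  expect_identical(sort(all_ids), sort(ids(ss)))
  sp2 <- split_dataset(ss, c(0.15, 0.15, 0.70), seed = 9)
  expect_identical(ids(sp2$train), ids(sp$train))
  # all-train degenerate split
  sp3 <- split_dataset(ss, c(0, 0, 1), seed = 1)
  expect_length(sp3$train, 40L)
  expect_length(sp3$test, 0L)
  # the 0.15 / 0.85 evaluation-style split
  sp4 <- split_dataset(ss, c(0.85, 0.15, 0), seed = 2)
  expect_length(sp4$validation, 6L)
  expect_length(sp4$test, 34L)
  expect_error(split_dataset(ss, c(0.5, 0.6, 0.2)), "summing to 1")
})

test_that("scalers standardise training data and never leak", {
  ss <- toy_sample_set(20, seed = 4)
  # shift so the data is clearly not standard
  ss <- lapply(ss, function(s) {
    s$raw_values <- s$raw_values * 7 + 50
    s$event_features <- s$event_features * 2 + 10
    s
  })
  sc <- fit_scalers(ss)
  scaled <- apply_scalers(ss, sc)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  raw_all <- unlist(lapply(scaled, `[[`, "raw_values"))
  expect_equal(mean(raw_all), 0, tolerance = 1e-10)
  expect_equal(pop_sd(raw_all), 1, tolerance = 1e-10)
  ev_all <- do.call(rbind, lapply(scaled, `[[`, "event_features"))
  expect_equal(unname(colMeans(ev_all)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(ev_all, 2, pop_sd)), rep(1, 5),
               tolerance = 1e-10)
  # z-score example: {1,3} standardises to {-1,+1} (population sd)
  one <- list(list(raw_values = c(1, 3), raw_len = 2L,
                   event_features = matrix(0, 1, 5), event_count = 1L))
  sc1 <- fit_scalers(one)
  z <- apply_scalers(one, sc1)[[1L]]$raw_values
  expect_equal(z, c(-1, 1))
  # constant feature -> floored sd -> zeros, no NaN
  expect_true(all(is.finite(apply_scalers(one, sc1)[[1L]]$event_features)))
  expect_equal(apply_scalers(one, sc1)[[1L]]$event_features,
               matrix(0, 1, 5))
  # scaler statistics depend only on the fitted (training) split
  other <- toy_sample_set(5, seed = 99)
  expect_identical(fit_scalers(ss)$mean, sc$mean)
  scaled_other <- apply_scalers(other, sc)
  expect_false(isTRUE(all.equal(
    mean(unlist(lapply(scaled_other, `[[`, "raw_values"))), 0,
    tolerance = 1e-6)))
})

test_that("batching pads, masks and chunks correctly", {
  ss <- toy_sample_set(10, seed = 6)
  bs <- make_batches(ss, batch_size = 4L, rawmax = 40L, eventmax = 6L)
  expect_length(bs, 3L)
  expect_identical(vapply(bs, `[[`, 1L, "n"), c(4L, 4L, 2L))
  b <- bs[[1L]]
  expect_identical(dim(b$raw), c(4L, 40L))
  expect_identical(dim(b$events), c(4L, 6L, 5L))
  for (i in 1:4) {
    s <- ss[[i]]
    expect_identical(sum(b$raw_mask[i, ]), as.double(s$raw_len))
    expect_identical(sum(b$event_mask[i, ]), as.double(s$event_count))
    expect_identical(sum(b$target_mask[i, ]), as.double(length(s$tokens)))
    # padding regions are exactly zero / PAD
    expect_true(all(b$raw[i, b$raw_mask[i, ] == 0] == 0))
    expect_true(all(b$target[i, b$target_mask[i, ] == 0] == 0L))
    # PAD never inside the START..END span
    toks <- b$target[i, seq_len(length(s$tokens))]
    expect_false(any(toks == 0L))
    # masked mean equals true mean (mask contract)
    expect_equal(sum(b$raw[i, ]) / sum(b$raw_mask[i, ]),
                 mean(s$raw_values))
  }
})
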