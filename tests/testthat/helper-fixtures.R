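# Shared fixtures: tiny random batches, toy models, and small simulated
# corpora.  Everything is generated in code under fixed seeds.

# A synthetic scaled/tokenized sample with given sizes (already "scaled":
# values are N(0,1) draws, so make_batches can consume it directly).
toy_sample <- function(raw_len, event_count, bases, seed) {
  withr_seed <- function(expr) squigglecall:::with_seed(seed, expr)
  withr_seed(list(
    raw_values = stats::rnorm(raw_len),
    raw_len = raw_len,
    event_features = matrix(stats::rnorm(event_count * 5), event_count, 5),
    event_count = event_count,
    raw_span = c(0L, raw_len),
    tokens = tokenize(bases),
    bases = bases))
}

random_bases <- function(n, seed) {
  squigglecall:::with_seed(seed,
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# Small toy sample set for model tests (rawmax 40, eventmax 6).
toy_sample_set <- function(n = 10L, seed = 1L) {
  lapply(seq_len(n), function(i)
    toy_sample(raw_len = 20L + (i %% 3L) * 10L, event_count = 3L + (i %% 4L),
               bases = random_bases(4L + (i %% 3L), seed + 100L + i),
               seed = seed + i))
}

toy_batch <- function(samples, rawmax = 40L, eventmax = 6L,
                      batch_size = 64L) {
  make_batches(samples, batch_size, rawmax, eventmax)[[1L]]
}

tiny_model <- function(mode = "joint", latent = 6L, rawmax = 40L,
                       eventmax = 6L, seed = 7L, decode_max = 8L) {
  init_model(model_config(latent_dim = latent, mode = mode, rawmax = rawmax,
                          eventmax = eventmax, decode_max = decode_max),
             seed = seed)
}

# Cache expensive trained models across tests within one run.
.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# Scaled-down simulated corpus: two sequences (train / eval) from one basis,
# mirroring the reduced-complexity dataset recipe at desk scale.
sim_corpus <- function(num_basic, train_len, eval_len, read_length = 300L,
                       noise_sd = 2.0, seed = 11L) {
  basis <- generate_kmer_basis(num_basic, seed = seed)
  pm <- pore_model(seed = seed, noise_sd = noise_sd)
  side <- function(len, off, prefix) {
    ref <- generate_reference(basis, len, seed = seed + off)
    n <- len / read_length
    reads <- lapply(seq_len(n), function(i) {
      sub <- substr(ref$sequence, (i - 1L) * read_length + 1L,
                    i * read_length)
      simulate_signal(sub, pm, seed = seed + off + 10L * i,
                      read_id = sprintf("%s_%03d", prefix, i))
    })
    reads
  }
  list(train = side(train_len, 1L, "trn"), eval = side(eval_len, 2L, "evl"),
       basis = basis, pore = pm)
}
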