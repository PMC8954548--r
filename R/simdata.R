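# Reduced-complexity reference generation and pore-model squiggle simulation.
#
# References are built as random variations with repetition of a small set of
# "basic" 6-mers drawn from a seeded permutation of all 4^6 = 4096 6-mers, so
# that dataset complexity (measured by restricted linguistic complexity) can be
# dialled from trivial to fully random.  Simulated raw signal emulates a
# nanopore squiggle: each base dwells in the pore for a random number of raw
# samples (mean ~8) while the current sits at the level of the 6-mer currently
# occupying the pore, plus Gaussian noise.  Per-base raw index ranges are kept
# as ground truth for training and evaluation.

DNA_ALPHABET <- c("A", "C", "G", "T")
KMER_K <- 6L
N_KMERS <- 4096L  # 4^6

#' All 4096 DNA 6-mers in lexicographic order
#' @return character vector of length 4096
#' @keywords internal
all_kmers <- function() {
  grid <- expand.grid(rep(list(DNA_ALPHABET), KMER_K),
                      stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reorder so the first
  # character is the slowest digit, giving lexicographic order
  apply(grid[, KMER_K:1, drop = FALSE], 1L, paste0, collapse = "")
}

#' Generate a nested basis of basic 6-mers
#'
#' Takes the first `num_basic` elements of a seed-determined random permutation
#' of all 4096 6-mers.  For a fixed seed, bases are nested: a larger basis
#' contains every smaller basis as a prefix, so dataset family members share
#' their simplest vocabulary.
#'
#' @param num_basic number of basic 6-mers, in 1..4096
#' @param seed integer seed controlling the permutation
#' @return object of class `kmer_basis`: list with `k`, `members`, `seed`
#' @export
#' @examples
#' b <- generate_kmer_basis(3, seed = 1)
#' b$members
generate_kmer_basis <- function(num_basic, seed = 1L) {
  if (!is.numeric(num_basic) || length(num_basic) != 1L ||
      num_basic < 1L || num_basic > N_KMERS || num_basic != floor(num_basic)) {
    stop("`num_basic` must be a single integer in 1..4096")
  }
  num_basic <- as.integer(num_basic)
  perm <- with_seed(seed, sample.int(N_KMERS))
  members <- all_kmers()[perm][seq_len(num_basic)]
  structure(list(k = KMER_K, members = members, seed = as.integer(seed)),
            class = "kmer_basis")
}

#' @export
print.kmer_basis <- function(x, ...) {
  cat(sprintf("<kmer_basis> %d basic %d-mers (seed %d)\n",
              length(x$members), x$k, x$seed))
  cat(" first members:", paste(utils::head(x$members, 5L), collapse = " "),
      if (length(x$members) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Generate a reference sequence from a 6-mer basis
#'
#' The sequence is a random variation with repetition of the basic 6-mers:
#' `length/6` independent uniform draws from the basis, concatenated.  The
#' length must therefore be a positive multiple of 6.
#'
#' @param basis a `kmer_basis`
#' @param length total sequence length in bases (positive multiple of 6)
#' @param seed integer seed for the draws
#' @return object of class `reference_sequence`: list with `sequence`,
#'   `length`, `source_basis_size`
#' @export
generate_reference <- function(basis, length, seed = 1L) {
  stopifnot(inherits(basis, "kmer_basis"))
  if (!is.numeric(length) || length(length) != 1L || length <= 0 ||
      length != floor(length) || (length %% KMER_K) != 0) {
    stop("`length` must be a positive multiple of 6")
  }
  n_blocks <- as.integer(length / KMER_K)
  idx <- with_seed(seed, sample.int(length(basis$members), n_blocks,
                                    replace = TRUE))
  structure(list(sequence = paste0(basis$members[idx], collapse = ""),
                 length = as.integer(length),
                 source_basis_size = length(basis$members)),
            class = "reference_sequence")
}

#' Count distinct k-mers appearing in a sequence
#'
#' Counts distinct length-`k` substrings over all positions (sliding window,
#' stride 1), i.e. the observed vocabulary size.
#'
#' @param seq character scalar over A/C/G/T (other symbols are allowed and
#'   simply counted as-is)
#' @param k word length
#' @return integer count of distinct k-mers
#' @export
count_appearing_kmers <- function(seq, k = KMER_K) {
  seq <- as_sequence_string(seq)
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than k")
  starts <- seq_len(n - k + 1L)
  length(unique(substring(seq, starts, starts + k - 1L)))
}

#' Restricted linguistic complexity
#'
#' Linguistic sequence complexity with the vocabulary restricted to words of
#' size `k`: the number of distinct k-mers observed divided by the maximum
#' possible for the sequence length, `min(4^k, nchar(seq) - k + 1)`.
#'
#' @inheritParams count_appearing_kmers
#' @return fraction in (0, 1]
#' @export
linguistic_complexity <- function(seq, k = KMER_K) {
  seq <- as_sequence_string(seq)
  observed <- count_appearing_kmers(seq, k)
  observed / min(4^k, nchar(seq) - k + 1L)
}

#' Build a synthetic pore model
#'
#' Maps each of the 4096 6-mers to a mean current level (pA), drawn once from
#' Normal(level_mean, level_sd) and clipped positive, plus a per-6-mer level
#' spread (0 by default, so `noise_sd = 0` gives a noiseless squiggle).  Dwell
#' time per base is geometric (memoryless) with the given mean, or constant.
#'
#' @param seed integer seed making the level table reproducible
#' @param dwell_mean expected raw samples per base (>= 1); nanopore raw data
#'   typically carries ~8 samples per base
#' @param noise_sd additive Gaussian noise scale in pA (>= 0)
#' @param level_mean,level_sd distribution of per-6-mer current levels (pA)
#' @param level_spread per-6-mer level spread in pA added in quadrature with
#'   `noise_sd`
#' @param dwell one of "geometric" (default) or "constant"
#' @return object of class `pore_model`
#' @export
pore_model <- function(seed = 1L, dwell_mean = 8, noise_sd = 2.0,
                       level_mean = 100, level_sd = 15, level_spread = 0,
                       dwell = c("geometric", "constant")) {
  dwell <- match.arg(dwell)
  stopifnot(dwell_mean >= 1, noise_sd >= 0, level_spread >= 0)
  levels <- with_seed(seed, pmax(1, stats::rnorm(N_KMERS, level_mean, level_sd)))
  names(levels) <- all_kmers()
  structure(list(levels = levels,
                 spread = rep(level_spread, N_KMERS),
                 dwell_mean = dwell_mean,
                 noise_sd = noise_sd,
                 dwell = dwell,
                 seed = as.integer(seed)),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf(
    "<pore_model> 4096 6-mer levels (seed %d), dwell %s mean %.1f, noise sd %.2f pA\n",
    x$seed, x$dwell, x$dwell_mean, x$noise_sd))
  invisible(x)
}

# 6-mer occupying the pore while base j translocates: the window starting at
# j - 2 (1-based), clamped to the sequence ends, so the base sits near the
# centre of the 6-mer.
centered_kmer_starts <- function(m) {
  pmin(pmax(seq_len(m) - 2L, 1L), m - KMER_K + 1L)
}

#' Simulate a raw nanopore read from a reference
#'
#' For each base j a dwell d_j >= 1 raw samples is drawn (geometric with the
#' model's mean, or constant); the signal sits at the current level of the
#' 6-mer centred on base j plus Gaussian noise.  Ground-truth per-base raw
#' ranges are recorded as 0-based half-open intervals partitioning the signal.
#'
#' @param ref a `reference_sequence` (or plain character over A/C/G/T with
#'   length >= 6)
#' @param model a `pore_model`
#' @param seed integer seed for dwell and noise draws
#' @param read_id identifier stored with the read
#' @return object of class `raw_read`: list with `read_id`, `signal` (pA),
#'   `reference` (character), `truth_ranges` (data.frame base_index, base,
#'   raw_start, raw_end; 0-based half-open)
#' @export
simulate_signal <- function(ref, model, seed = 1L, read_id = "read_001") {
  seq <- if (inherits(ref, "reference_sequence")) ref$sequence else
    as_sequence_string(ref)
  m <- nchar(seq)
  if (m == 0L) stop("empty reference")
  if (m < KMER_K) stop("reference shorter than 6 bases")
  starts <- centered_kmer_starts(m)
  kmers <- substring(seq, starts, starts + KMER_K - 1L)
  mu <- unname(model$levels[kmers])
  if (anyNA(mu)) stop("pore model does not cover all 6-mers of the reference")
  spread <- unname(model$spread[match(kmers, names(model$levels))])
  sd_j <- sqrt(model$noise_sd^2 + spread^2)

  sim <- with_seed(seed, {
    d <- if (model$dwell == "constant") {
      rep(as.integer(round(model$dwell_mean)), m)
    } else {
      # geometric shifted to minimum 1 with mean dwell_mean
      1L + stats::rgeom(m, prob = 1 / model$dwell_mean)
    }
    noise <- stats::rnorm(sum(d), 0, rep(sd_j, times = d))
    list(d = d, noise = noise)
  })
  d <- sim$d
  signal <- pmax(0, rep(mu, times = d) + sim$noise)
  raw_end <- cumsum(d)
  truth <- data.frame(
    base_index = seq_len(m) - 1L,
    base = strsplit(seq, "", fixed = TRUE)[[1L]],
    raw_start = c(0L, raw_end[-m]),
    raw_end = as.integer(raw_end),
    stringsAsFactors = FALSE)
  structure(list(read_id = read_id, signal = signal, reference = seq,
                 truth_ranges = truth),
            class = "raw_read")
}

#' @export
print.raw_read <- function(x, ...) {
  cat(sprintf("<raw_read> %s: %d raw samples, %d bases (n/m = %.2f)\n",
              x$read_id, length(x$signal), nchar(x$reference),
              length(x$signal) / nchar(x$reference)))
  invisible(x)
}

#' Simulate a dataset of reads from one reference
#'
#' Splits a freshly generated reference into consecutive reads of
#' `read_length` bases and simulates a squiggle for each.  This is the
#' reduced-complexity dataset recipe used throughout: pick a basis size, a
#' total length, and simulate.
#'
#' @param num_basic basis size (number of basic 6-mers)
#' @param total_length reference length in bases (multiple of `read_length`)
#' @param read_length bases per read (positive multiple of 6)
#' @param model a `pore_model`
#' @param seed integer master seed (basis, reference and reads derive from it)
#' @param id_prefix read identifier prefix
#' @return list with `basis`, `reference` (full sequence), `reads`
#'   (list of `raw_read`)
#' @export
simulate_dataset <- function(num_basic, total_length, read_length = 300L,
                             model = pore_model(), seed = 1L,
                             id_prefix = "sim") {
  stopifnot(read_length %% KMER_K == 0, total_length %% read_length == 0)
  basis <- generate_kmer_basis(num_basic, seed = seed)
  ref <- generate_reference(basis, total_length, seed = seed + 1L)
  n_reads <- total_length / read_length
  reads <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    sub <- substr(ref$sequence, (i - 1L) * read_length + 1L, i * read_length)
    reads[[i]] <- simulate_signal(sub, model, seed = seed + 1000L + i,
                                  read_id = sprintf("%s_%04d", id_prefix, i))
  }
  list(basis = basis, reference = ref$sequence, reads = reads)
}

#' De Bruijn sequence over the DNA alphabet
#'
#' Standard Lyndon-word ("FKM") construction of a cyclic sequence of length
#' `4^k` in which every k-mer over A/C/G/T occurs exactly once.  Useful for
#' building sequences with an exactly known 6-mer vocabulary: repeating the
#' order-(k-1) cycle gives a long sequence whose distinct k-mer count is
#' exactly `4^(k-1)`.
#'
#' @param k word order
#' @return character scalar of length `4^k` (one period of the cycle)
#' @export
debruijn_sequence <- function(k) {
  stopifnot(k >= 1, k <= 8)
  n <- 4L
  a <- integer(k * n)
  out <- integer(0)
  db <- function(t, p) {
    if (t > k) {
      if (k %% p == 0L) out <<- c(out, a[2:(p + 1L)])
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      db(t + 1L, p)
      j0 <- a[t - p + 1L] + 1L
      if (j0 <= n - 1L) {
        for (j in j0:(n - 1L)) {
          a[t + 1L] <<- j
          db(t + 1L, t)
        }
      }
    }
  }
  db(1L, 1L)
  paste0(DNA_ALPHABET[out + 1L], collapse = "")
}

# -- helpers ------------------------------------------------------------------

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package internals never disturb user randomness.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

as_sequence_string <- function(seq) {
  if (inherits(seq, "reference_sequence")) return(seq$sequence)
  if (!is.character(seq) || length(seq) != 1L)
    stop("expected a single character string")
  seq
}
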