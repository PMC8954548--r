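test_that("kmer basis is deterministic, nested, and validated", {
  b1 <- generate_kmer_basis(3, seed = 42)
  b2 <- generate_kmer_basis(12, seed = 42)
  expect_length(b1$members, 3L)
  expect_true(all(nchar(b2$members) == 6L))
  expect_false(anyDuplicated(b2$members) > 0L)
  # nesting: smaller basis is a prefix of the larger one (same seed)
  expect_identical(b1$members, b2$members[1:3])
  expect_identical(generate_kmer_basis(12, seed = 42)$members, b2$members)
  # different seed gives a different permutation (overwhelmingly)
  expect_false(identical(generate_kmer_basis(12, seed = 43)$members,
                         b2$members))
  b_all <- generate_kmer_basis(4096, seed = 1)
  expect_length(unique(b_all$members), 4096L)
  expect_length(generate_kmer_basis(1, seed = 1)$members, 1L)
  expect_error(generate_kmer_basis(0), "1\\.\\.4096")
  expect_error(generate_kmer_basis(4097), "1\\.\\.4096")
})

test_that("basis nesting holds across seeds and sizes (property)", {
  for (seed in c(1, 7, 123)) {
    sizes <- c(2L, 5L, 17L, 100L)
    bases <- lapply(sizes, generate_kmer_basis, seed = seed)
    for (i in 1:3)
      expect_identical(bases[[i]]$members,
                       bases[[i + 1L]]$members[seq_along(bases[[i]]$members)])
  }
})

test_that("reference generation follows the variation-with-repetition rule", {
  b1 <- structure(list(k = 6L, members = "AAAAAA", seed = 1L),
                  class = "kmer_basis")
  expect_identical(generate_reference(b1, 12, seed = 1)$sequence,
                   "AAAAAAAAAAAA")
  b <- generate_kmer_basis(4, seed = 3)
  r <- generate_reference(b, 60, seed = 9)
  expect_identical(nchar(r$sequence), 60L)
  # every aligned 6-mer block is a basis member
  blocks <- substring(r$sequence, seq(1, 55, by = 6), seq(6, 60, by = 6))
  expect_true(all(blocks %in% b$members))
  expect_identical(generate_reference(b, 60, seed = 9)$sequence, r$sequence)
  expect_error(generate_reference(b, 7), "multiple of 6")
  expect_error(generate_reference(b, 0), "multiple of 6")
})

test_that("k-mer counting and linguistic complexity", {
  expect_identical(count_appearing_kmers("AAAAAAAA", 6), 1L)
  expect_identical(count_appearing_kmers("ACGTAC", 6), 1L)
  expect_error(count_appearing_kmers("ACGTA", 6), "shorter")
  # len 6 sequence: denominator min(4096, 1) = 1
  expect_equal(linguistic_complexity("ACGTAC"), 1.0)
  # monotone under concatenation (property)
  s1 <- random_bases(100, 5)
  for (seed in 6:9) {
    s2 <- paste0(s1, random_bases(50, seed))
    expect_gte(count_appearing_kmers(s2, 6), count_appearing_kmers(s1, 6))
  }
  # bounds
  expect_gt(linguistic_complexity(s1), 0)
  expect_lte(linguistic_complexity(s1), 1)
})

test_that("de Bruijn repetition gives an exactly known 6-mer vocabulary", {
  # one period of the order-5 cycle has 1024 distinct (cyclic) 6-mer windows;
  # repeating it yields a long sequence with exactly 1024 distinct 6-mers
  db5 <- debruijn_sequence(5)
  expect_identical(nchar(db5), 1024L)
  long <- paste0(strrep(db5, 5L))
  expect_identical(count_appearing_kmers(long, 6), 1024L)
  expect_equal(linguistic_complexity(long), 1024 / 4096)
})

test_that("signal simulation: constant dwell, noiseless case is exact", {
  b <- generate_kmer_basis(2, seed = 1)
  ref <- generate_reference(b, 30, seed = 2)  # m = 30 bases
  pm <- pore_model(seed = 1, noise_sd = 0, dwell = "constant")
  rd <- simulate_signal(ref, pm, seed = 3)
  expect_length(rd$signal, 240L)  # 8 x 30
  expect_identical(nrow(rd$truth_ranges), 30L)
  # piecewise constant within each truth range
  for (i in c(1L, 10L, 30L)) {
    seg <- rd$signal[(rd$truth_ranges$raw_start[i] + 1L):
                       rd$truth_ranges$raw_end[i]]
    expect_equal(stats::sd(seg), 0)
  }
  expect_error(simulate_signal("", pm), "empty")
})

test_that("truth ranges partition [0, n) for random reads (property)", {
  pm <- pore_model(seed = 2, noise_sd = 1.5)
  b <- generate_kmer_basis(5, seed = 4)
  for (seed in c(1, 2, 3)) {
    ref <- generate_reference(b, 120, seed = seed)
    rd <- simulate_signal(ref, pm, seed = seed + 10)
    tr <- rd$truth_ranges
    n <- length(rd$signal)
    expect_identical(tr$raw_start[1L], 0L)
    expect_identical(tr$raw_end[nrow(tr)], n)
    expect_true(all(tr$raw_start[-1L] == tr$raw_end[-nrow(tr)]))
    expect_true(all(tr$raw_end > tr$raw_start))
    expect_identical(sum(tr$raw_end - tr$raw_start), n)
    # determinism
    rd2 <- simulate_signal(ref, pm, seed = seed + 10)
    expect_identical(rd2$signal, rd$signal)
  }
})

test_that("mean dwell approaches 8 raw samples per base", {
  b <- generate_kmer_basis(50, seed = 6)
  ref <- generate_reference(b, 10002, seed = 7)
  rd <- simulate_signal(ref, pore_model(seed = 1), seed = 8)
  ratio <- length(rd$signal) / nchar(rd$reference)
  expect_lt(abs(ratio - 8) / 8, 0.02)
})
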