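# Brute-force alignment oracle: enumerate all global alignments recursively
# (no DP) and return the maximum score.  Exponential, so only for tiny inputs.
brute_align_score <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  rec <- function(i, j) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, (if (av[i] == bv[j]) match else mismatch) +
                    rec(i + 1L, j + 1L))
    if (i <= length(av)) best <- max(best, gap + rec(i + 1L, j))
    if (j <= length(bv)) best <- max(best, gap + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}

test_that("Needleman-Wunsch basics", {
  al <- needleman_wunsch("ACGT", "ACGT")
  expect_identical(al$score, 4)
  expect_identical(al$matches, 4L)
  expect_identical(al$alignment_length, 4L)
  al2 <- needleman_wunsch("ACGT", "")
  expect_identical(al2$score, -4)
  expect_identical(al2$alignment_length, 4L)
  al3 <- needleman_wunsch("ACGT", "ACGGT")
  expect_identical(al3$score, 3)
  expect_identical(al3$matches, 4L)
  expect_identical(al3$alignment_length, 5L)
  # removing gaps restores the inputs
  expect_identical(gsub("-", "", al3$aligned_a), "ACGT")
  expect_identical(gsub("-", "", al3$aligned_b), "ACGGT")
})

test_that("NW matches the brute-force enumeration oracle (2-letter, len<=6)", {
  seqs <- squigglecall:::with_seed(31, {
    lapply(1:24, function(i) {
      n1 <- sample(0:6, 1); n2 <- sample(0:6, 1)
      c(paste0(sample(c("A", "C"), n1, replace = TRUE), collapse = ""),
        paste0(sample(c("A", "C"), n2, replace = TRUE), collapse = ""))
    })
  })
  for (p in seqs) {
    nw <- needleman_wunsch(p[1], p[2])
    expect_identical(nw$score, brute_align_score(p[1], p[2]))
    # symmetry of the optimal score
    expect_identical(needleman_wunsch(p[2], p[1])$score, nw$score)
  }
})

test_that("merge_samples reconstructs exact overlapping windows (property)", {
  for (seed in 1:5) {
    ref <- random_bases(60 + seed * 10, seed + 40)
    for (w in c(18, 25)) {
      for (stride in c(4, 9)) {
        starts <- seq(1, nchar(ref) - w + 1, by = stride)
        frags <- vapply(starts, function(s) substr(ref, s, s + w - 1), "")
        # extend the final fragment to the reference end
        frags[length(frags)] <- substr(ref, starts[length(starts)],
                                       nchar(ref))
        got <- merge_samples(frags)
        expect_identical(got$sequence, ref)
      }
    }
  }
})

test_that("merge resolves overlap conflicts in favour of the earlier read", {
  ref <- "ACGTACGGTTCA"
  f1 <- substr(ref, 1, 8)    # ACGTACGG
  f2 <- substr(ref, 5, 12)   # ACGGTTCA
  sub <- f2
  substr(sub, 2, 2) <- "A"   # substitution inside the overlap
  got <- merge_samples(c(f1, sub, substr(ref, 9, 12)))
  expect_identical(got$sequence, ref)  # earlier base kept, length preserved
  # single sample passes through; empty ones are skipped with a message
  expect_identical(merge_samples("ACGT")$sequence, "ACGT")
  expect_message(m <- merge_samples(c("ACGT", "")), "empty")
  expect_identical(m$sequence, "ACGT")
  expect_error(merge_samples(character(0)), "no predictions")
})

test_that("subset accuracy definition", {
  expect_equal(subset_accuracy("ACGT", "ACGT"), 1)
  expect_equal(subset_accuracy("ACGT", "ACGA"), 0.75)
  expect_equal(subset_accuracy("AC", "ACGT"), 0.5)
  expect_equal(subset_accuracy("", ""), 1)
  expect_equal(subset_accuracy("", "ACGT"), 0)
})

test_that("read accuracy is BLAST identity with block-length weighting", {
  expect_equal(read_accuracy("ACGT", "ACGT")$identity, 1)
  ra <- read_accuracy("ACGT", "ACGGT")
  expect_equal(ra$identity, 0.8)
  expect_identical(ra$block_length, 5L)
  expect_equal(weighted_identity(c(0.90, 1.00), c(100, 300)), 0.975)
  # invariance: identity of x vs x is 1 for random sequences
  for (seed in 1:3)
    expect_equal(read_accuracy(random_bases(30, seed),
                               random_bases(30, seed))$identity, 1)
  # weighted mean bounded by min/max
  ids <- c(0.7, 0.9, 0.95); w <- c(10, 200, 50)
  wm <- weighted_identity(ids, w)
  expect_gte(wm, min(ids)); expect_lte(wm, max(ids))
  expect_error(read_accuracy("", "ACGT"), "nonempty")
})

test_that("evaluate_reads aggregates per-read identities", {
  reads <- list(
    structure(list(read_id = "a", sequence = "ACGTACGT", n_samples = 2L),
              class = "assembled_read"),
    structure(list(read_id = "b", sequence = "ACGT", n_samples = 1L),
              class = "assembled_read"))
  refs <- c(a = "ACGTACGT", b = "ACGGT")
  rep <- evaluate_reads(reads, refs)
  expect_identical(nrow(rep$per_read), 2L)
  expect_equal(rep$per_read$identity, c(1, 0.8))
  expect_equal(rep$weighted_identity, (1 * 8 + 0.8 * 5) / 13)
})

test_that("comparison summary reproduces known report arithmetic", {
  tbl <- expand.grid(dataset = c("d1", "d2"), mode = c("event", "raw",
                                                       "joint"),
                     beam_width = c(1L, 5L), stringsAsFactors = FALSE)
  # accuracies chosen so the expected means are easy closed forms
  tbl$accuracy <- c(70, 71, 80, 80.4, 81, 81.6,
                    72, 73, 80.2, 81.0, 82, 82.2)
  s <- accuracy_comparison_summary(tbl)
  imp <- c(2, 2, 0.2, 0.6, 1, 0.6)  # beam5 - beam1 per dataset x mode
  expect_equal(s$beam_improvement_all, mean(imp))
  expect_equal(s$beam_improvement_restricted, mean(imp[3:6]))
  adv <- c(81 - 80, 81.6 - 80.4, 82 - 80.2, 82.2 - 81.0)
  expect_equal(s$mode_advantage_all, mean(adv))
  expect_equal(s$mode_advantage_wide, mean(adv[3:4]))
})
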