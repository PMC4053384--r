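find_seed <- function(read, ref, pos0, K = 14) {
  # read was cut from ref at pos0; return an offset where a K-window is
  # still exact, or NA
  for (roff in 0:(nchar(read) - K))
    if (substr(read, roff + 1, roff + K) ==
        substr(ref, pos0 + roff + 1, pos0 + roff + K))
      return(roff)
  NA_integer_
}

test_that("a read identical to its window extends to a full-read bracket", {
  set.seed(701)
  ref <- random_dna(600)
  read <- substr(ref, 201, 300)
  e <- fuzzy_extend(read, ref, list(read_offset = 40, pos = 240,
                                    seed_len = 14))
  expect_true(e$passed)
  expect_equal(c(e$read_start, e$read_end), c(0L, 100L))
  expect_equal(c(e$ref_start, e$ref_end), c(200L, 300L))
  expect_equal(e$n_mismatch + e$n_ins + e$n_del, 0L)
  expect_equal(e$score, 100L)
  expect_equal(e$margin, -1)                   # margin >= 0 iff failed
})

test_that("substitutions at both read ends stay inside the bracket", {
  set.seed(702)
  ref <- random_dna(600)
  read <- mutate_subs(substr(ref, 201, 300), c(1, 100))
  expect_equal(utils::adist(read, substr(ref, 201, 300))[1, 1], 2L)  # oracle
  e <- fuzzy_extend(read, ref, list(read_offset = 40, pos = 240,
                                    seed_len = 14))
  expect_true(e$passed)
  expect_equal(e$n_mismatch, 2L)
  expect_equal(c(e$read_start, e$read_end), c(0L, 100L))
})

test_that("seed-only random flanks fail the minimum-length filter", {
  set.seed(703)
  for (trial in 1:10) {
    ref <- random_dna(600)
    read <- paste0(random_dna(43), substr(ref, 301, 314), random_dna(43))
    e <- fuzzy_extend(read, ref, list(read_offset = 43, pos = 300,
                                      seed_len = 14))
    expect_false(e$passed)
    expect_gte(e$margin, 0)
  }
})

test_that("seed verification and range errors are raised", {
  ref <- strrep("ACGT", 50)
  expect_error(fuzzy_extend("TTTTTTTTTTTTTTTT", ref,
                            list(read_offset = 0, pos = 0, seed_len = 14)),
               "verify")
  expect_error(fuzzy_extend("ACGT", ref,
                            list(read_offset = 2, pos = 0, seed_len = 14)),
               "outside")
})

test_that("loosening thresholds can only turn fails into passes", {
  set.seed(704)
  strict <- extension_params(min_len_pct = 75, mismatch_pct = 15)
  loose <- extension_params(min_len_pct = 50, mismatch_pct = 25)
  for (trial in 1:200) {
    ref <- random_dna(400)
    pos0 <- sample(50:250, 1)
    read <- substr(ref, pos0 + 1, pos0 + 100)
    nerr <- sample(0:20, 1)
    if (nerr) read <- mutate_subs(read, sample(1:100, nerr))
    roff <- find_seed(read, ref, pos0)
    if (is.na(roff)) next
    hit <- list(read_offset = roff, pos = pos0 + roff, seed_len = 14)
    es <- fuzzy_extend(read, ref, hit, strict)
    el <- fuzzy_extend(read, ref, hit, loose)
    if (es$passed) expect_true(el$passed)
  }
})

test_that("the filter never rejects a pair the optimal aligner would report", {
  # over >= 10^4 random seeded pairs at default parameters, any pair whose
  # full Smith-Waterman alignment (independent oracle) meets the reporting
  # thresholds must pass the extension filter; violations must be zero
  set.seed(705)
  min_report <- ceiling(36 * (5 * 0.85 - 4 * 0.15))  # default thresholds
  n_pairs <- 10000
  fails <- list()
  for (trial in seq_len(n_pairs)) {
    ref <- random_dna(260)
    pos0 <- sample(20:120, 1)
    read <- substr(ref, pos0 + 1, pos0 + 100)
    nerr <- sample(0:18, 1)
    if (nerr) read <- mutate_subs(read, sample(1:100, nerr))
    roff <- find_seed(read, ref, pos0)
    if (is.na(roff)) next
    e <- fuzzy_extend(read, ref, list(read_offset = roff, pos = pos0 + roff,
                                      seed_len = 14))
    if (!e$passed) fails[[length(fails) + 1]] <- c(trial, read = read,
                                                   ref = ref)
  }
  # oracle check only needed on filtered-out pairs: a violation is a pair
  # whose full-SW optimal alignment meets all reporting thresholds
  # (minimal score, minimal aligned read length, mismatch+indel fraction)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4)
  violations <- 0L
  for (f in fails) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(f[["read"]]), Biostrings::DNAString(f[["ref"]]),
      type = "local", substitutionMatrix = mat, gapOpening = 12,
      gapExtension = 2)
    nmat <- Biostrings::nmatch(pa)
    nmis <- Biostrings::nmismatch(pa)
    ind <- sum(Biostrings::nindel(pa)@insertion[, 2],
               Biostrings::nindel(pa)@deletion[, 2])
    cols <- nmat + nmis + ind
    span <- nmat + nmis + sum(Biostrings::nindel(pa)@insertion[, 2])
    if (Biostrings::score(pa) >= min_report && span >= 36 &&
        (nmis + ind) / cols <= 0.15)
      violations <- violations + 1L
  }
  expect_equal(violations, 0L)
})

test_that("failed extensions report a margin consistent with the shortfall", {
  set.seed(706)
  ref <- random_dna(400)
  read <- paste0(random_dna(40), substr(ref, 201, 214), random_dna(46))
  e <- fuzzy_extend(read, ref, list(read_offset = 40, pos = 200,
                                    seed_len = 14))
  expect_false(e$passed)
  required <- ceiling(75 * (1 - 2 * 0.15))  # minimal passing extension score
  expect_equal(e$margin, max(0, required - e$score))
})
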