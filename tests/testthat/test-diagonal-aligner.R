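test_that("a perfect 50-base read scores 50 matches", {
  set.seed(801)
  ref <- random_dna(200)
  read <- substr(ref, 51, 100)
  al <- band_align(read, ref, c(0, 50, 40, 120), min_match_len = 36,
                   center0 = 10)
  expect_equal(al$score, 250L)
  expect_equal(al$cigar, "50M")
  expect_equal(al$ref_start, 50L)
  expect_equal(al$ref_end, 100L)
  expect_true(al$passed)
})

test_that("a single-cell optimum gives a length-1 trajectory", {
  al <- band_align("A", "GGAGG", c(0, 1, 0, 5), min_match_len = 1, w = 4)
  expect_equal(al$score, 5L)
  expect_equal(al$ops, "M")
  expect_equal(al$ref_start, 2L)
})

test_that("floating band recovers multi-indel optima a fixed band cannot", {
  set.seed(802)
  base <- random_dna(200)
  read <- substr(base, 1, 90)
  # three separated 3-base reference insertions: each excursion <= w,
  # cumulative excursion 9 > w = 4
  refmod <- base
  for (at in c(75, 50, 25))
    refmod <- paste0(substr(refmod, 1, at), "TGA",
                     substr(refmod, at + 1, nchar(refmod)))
  br <- c(0, 90, 0, nchar(refmod))
  fl <- band_align(read, refmod, br, w = 4, min_match_len = 20,
                   return_failed = TRUE)
  fx <- band_align(read, refmod, br, w = 4, min_match_len = 20,
                   float_band = FALSE, return_failed = TRUE)
  oracle <- oracle_sw_score(read, refmod)
  expect_equal(fl$score, as.integer(oracle))
  expect_lt(fx$score, fl$score)
  expect_equal(fl$n_del, 9L)
})

test_that("band scores equal full-matrix Smith-Waterman within excursion", {
  set.seed(803)
  n_diff <- 0L
  for (trial in 1:120) {
    ref <- random_dna(300)
    start <- sample(50:150, 1)
    read <- substr(ref, start, start + 79)
    v <- strsplit(read, "", fixed = TRUE)[[1]]
    nsub <- sample(0:6, 1)
    if (nsub) for (q in sample(10:70, nsub))
      v[q] <- sample(setdiff(DNA, v[q]), 1)
    if (runif(1) < 0.5) {
      p <- sample(20:60, 1); d <- sample(1:3, 1)
      v <- v[-(p:(p + d - 1))]
    }
    if (runif(1) < 0.5) {
      p <- sample(20:60, 1); d <- sample(1:3, 1)
      v <- append(v, sample(DNA, d, replace = TRUE), after = p)
    }
    rd <- paste(v, collapse = "")
    qs <- max(0, start - 11)
    qe <- min(nchar(ref), start - 1 + nchar(rd) + 10)
    al <- band_align(rd, ref, c(0, nchar(rd), qs, qe), w = 8,
                     min_match_len = 10, mismatch_pct = 40,
                     center0 = start - 1 - qs, return_failed = TRUE)
    osc <- oracle_sw_score(rd, substr(ref, qs + 1, qe))
    if (al$score != osc) n_diff <- n_diff + 1L
    expect_equal(al$score_recomputed, al$score)  # score == sum(P_l)
  }
  expect_equal(n_diff, 0L)
})

test_that("band agrees with a pure-R full-matrix oracle at tiny sizes", {
  set.seed(804)
  for (trial in 1:25) {
    a <- random_dna(sample(10:18, 1))
    b <- random_dna(sample(12:24, 1))
    al <- band_align(a, b, c(0, nchar(a), 0, nchar(b)), w = 24,
                     min_match_len = 1, mismatch_pct = 100,
                     return_failed = TRUE)
    expect_equal(al$score, oracle_sw_tiny(a, b))
  }
})

test_that("pruning changes computed cells but never the reported result", {
  set.seed(805)
  for (trial in 1:60) {
    ref <- random_dna(240)
    start <- sample(30:100, 1)
    read <- mutate_subs(substr(ref, start, start + 99),
                        sample(1:100, sample(0:10, 1)))
    br <- c(0, 100, max(0, start - 9), min(240, start + 107))
    a1 <- band_align(read, ref, br, center0 = start - 1 - br[3],
                     prune = TRUE, return_failed = TRUE)
    a0 <- band_align(read, ref, br, center0 = start - 1 - br[3],
                     prune = FALSE, return_failed = TRUE)
    expect_identical(a1$passed, a0$passed)
    expect_identical(a1$score, a0$score)
    expect_identical(a1$cigar, a0$cigar)
    expect_identical(a1$ref_start, a0$ref_start)
    expect_equal(a0$diagnostics$holes, 0)           # no pruning -> no holes
    expect_lte(a1$diagnostics$live_cells, a0$diagnostics$live_cells)
  }
})

test_that("live band storage never exceeds (2w+1) x L", {
  set.seed(806)
  ref <- random_dna(400)
  read <- substr(ref, 101, 200)
  for (w in c(2L, 8L, 16L)) {
    al <- band_align(read, ref, c(0, 100, 0, 400), w = w, center0 = 100,
                     return_failed = TRUE)
    expect_lte(al$diagnostics$live_cells, (2 * w + 1) * (100 + 1))
  }
})

test_that("the admissible upper bound includes the all-match completion", {
  sp <- scoring_params()
  expect_equal(score_upper_bound(0, 20, 0, sp), 100)
  expect_equal(score_upper_bound(37, 10, 0, sp), 87)
  # global mode pays the forced gap schedule for off-diagonal distance
  expect_equal(score_upper_bound(37, 10, 3, sp, global = TRUE),
               87 - 12 - 6)
})

test_that("global mode matches the full Needleman-Wunsch oracle", {
  set.seed(807)
  for (trial in 1:10) {
    a <- random_dna(40)
    b <- mutate_subs(a, sample(1:40, sample(0:6, 1)))
    al <- band_align(a, b, c(0, 40, 0, 40), mode = "global", w = 8,
                     min_match_len = 1, mismatch_pct = 100,
                     return_failed = TRUE)
    expect_equal(al$score, as.integer(oracle_sw_score(a, b, type = "global")))
    expect_equal(nchar(gsub("[^M]", "", al$ops)) +
                   nchar(gsub("[^X]", "", al$ops)), 40L)
  }
})

test_that("sub-threshold alignments are not reported", {
  set.seed(808)
  ref <- random_dna(300)
  read <- random_dna(60)  # unrelated read
  expect_null(band_align(read, ref, c(0, 60, 0, 300), min_match_len = 36))
  al <- band_align(read, ref, c(0, 60, 0, 300), min_match_len = 36,
                   return_failed = TRUE)
  expect_false(al$passed)
})
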