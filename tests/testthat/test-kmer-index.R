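test_that("bucket contents follow the direct-address layout", {
  idx <- build_kmer_index(c(r1 = "ACGTACGT"), k = 4)
  b <- index_bucket(idx, "ACGT")
  expect_equal(b$ref, c(0L, 0L))
  expect_equal(b$pos, c(0L, 4L))
  expect_true(b$bloom)
  expect_false(b$masked)
  b2 <- index_bucket(idx, "CGTA")
  expect_equal(b2$pos, 1L)
  b3 <- index_bucket(idx, "TTTT")
  expect_equal(length(b3$pos), 0L)
  expect_false(b3$bloom)                 # empty bucket -> presence bit 0
})

test_that("over-expressed buckets are masked, not deleted", {
  idx <- build_kmer_index(c(r = strrep("A", 100)), k = 4, threshold = 10)
  b <- index_bucket(idx, "AAAA")
  expect_equal(length(b$pos), 97L)       # 100 - 4 + 1 occurrences retained
  expect_true(b$masked)
  expect_true(b$bloom)                   # presence reflects pre-mask content
  lk <- lookup_seeds(idx, strrep("A", 20))
  expect_equal(nrow(lk$hits), 0L)        # masked buckets contribute no hits
  expect_gt(lk$counters$masked_skips, 0)
})

test_that("lookup is complete against a brute-force scan (unmasked, p=1)", {
  set.seed(601)
  for (trial in 1:5) {
    ref <- random_dna(300)
    read <- random_dna(40)
    # plant a shared window so hits exist
    at <- sample(1:250, 1)
    read <- paste0(substr(read, 1, 15), substr(ref, at, at + 9),
                   substr(read, 26, 40))
    K <- 6
    idx <- build_kmer_index(c(r = ref), k = K, threshold = 10000)
    lk <- lookup_seeds(idx, read)
    o <- oracle_kmer_hits(ref, read, K)
    # every exact common k-mer yields a hit on its diagonal
    expect_setequal(lk$hits$pos - lk$hits$read_offset, unique(o$diag))
    expect_equal(lk$counters$raw_hits, nrow(o))
    # diagonal dedup keeps the leftmost read offset
    for (i in seq_len(nrow(lk$hits))) {
      d <- lk$hits$pos[i] - lk$hits$read_offset[i]
      expect_equal(lk$hits$read_offset[i], min(o$roff[o$diag == d]))
      expect_equal(lk$hits$n_seeds[i], sum(o$diag == d))
    }
  }
})

test_that("presence-bit misses short-circuit bucket fetches", {
  idx <- build_kmer_index(c(r = strrep("A", 200)), k = 4)
  lk <- lookup_seeds(idx, strrep("T", 30))
  expect_equal(nrow(lk$hits), 0L)
  expect_equal(lk$counters$bloom_hits, 0)
  expect_equal(lk$counters$bucket_fetches, 0)   # zero fetches on misses
  set.seed(602)
  ref <- random_dna(2000)
  idx <- build_kmer_index(c(r = ref), k = 8)
  lk <- lookup_seeds(idx, random_dna(100))
  expect_lte(lk$counters$bucket_fetches, lk$counters$bloom_hits)
})

test_that("entry count matches the memory model exactly", {
  set.seed(603)
  lens <- c(137L, 54L, 301L)
  refs <- data.frame(id = paste0("r", 1:3),
                     seq = vapply(lens, random_dna, ""))
  K <- 7L
  for (p in c(1L, 3L)) {
    idx <- build_kmer_index(refs, k = K, step = p)
    expect_equal(index_info(idx)$n_entries, sum(ceiling((lens - K + 1) / p)))
  }
})

test_that("raising the masking threshold can only add hits", {
  set.seed(604)
  ref <- paste0(random_dna(500), strrep("AC", 100), random_dna(500))
  read <- paste0(strrep("AC", 20), substr(ref, 101, 160))
  key <- function(h) paste(h$ref, h$pos - h$read_offset)
  i1 <- build_kmer_index(c(r = ref), k = 6, threshold = 5)
  i2 <- build_kmer_index(c(r = ref), k = 6, threshold = 500)
  h1 <- lookup_seeds(i1, read)$hits
  h2 <- lookup_seeds(i2, read)$hits
  expect_true(all(key(h1) %in% key(h2)))
  expect_gt(nrow(h2), nrow(h1))
})

test_that("double lookup serves seeds longer than the index K", {
  set.seed(605)
  ref <- random_dna(3000)
  expect_error(build_kmer_index(c(r = ref), k = 16), "double-lookup")
  idx <- build_kmer_index(c(r = ref), k = 10)
  read <- substr(ref, 501, 580)
  h <- lookup_seeds(idx, read, seed_len = 20)$hits
  expect_true(any(h$pos - h$read_offset == 500))
  # a read sharing only a 10-mer matches at K=10 but not at seed_len=20
  read2 <- paste0(random_dna(30), substr(ref, 1001, 1010), random_dna(30))
  expect_true(any(lookup_seeds(idx, read2, 10)$hits$pos -
                    lookup_seeds(idx, read2, 10)$hits$read_offset == 970))
  h2 <- lookup_seeds(idx, read2, seed_len = 20)$hits
  expect_false(any(h2$pos - h2$read_offset == 970))
})

test_that("isolated N blocks overlapping seed windows only", {
  set.seed(606)
  ref <- random_dna(400)
  idx <- build_kmer_index(c(r = ref), k = 8)
  read <- substr(ref, 101, 160)
  substr(read, 30, 30) <- "N"
  lk <- lookup_seeds(idx, read)
  expect_equal(lk$counters$n_offsets, (60 - 8 + 1) - 8)  # 8 windows blocked
  expect_true(any(lk$hits$pos - lk$hits$read_offset == 100))
})

test_that("the optional entropy mask suppresses low-complexity regions", {
  set.seed(607)
  ref <- paste0(random_dna(256), strrep("A", 128), random_dna(256))
  plain <- build_kmer_index(c(r = ref), k = 8, threshold = 1e6)
  masked <- build_kmer_index(c(r = ref), k = 8, threshold = 1e6,
                             min_entropy = 1.5)
  expect_lt(index_info(masked)$n_entries, index_info(plain)$n_entries)
  expect_equal(length(index_bucket(masked, strrep("A", 8))$pos), 0L)
})
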