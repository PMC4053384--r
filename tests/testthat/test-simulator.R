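test_that("reference simulation is reproducible and validates input", {
  expect_error(simulate_reference(0), ">= 1")
  a <- simulate_reference(500, seed = 9)
  b <- simulate_reference(500, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a$seq, simulate_reference(500, seed = 10)$seq))
})

test_that("simulated base composition is uniform at 1 Mb", {
  r <- simulate_reference(1e6, seed = 77)
  freq <- table(strsplit(r$seq, "", fixed = TRUE)[[1]]) / 1e6
  expect_true(all(abs(freq - 0.25) < 0.005))  # binomial bound at n = 10^6
})

test_that("error-free reads are exact substrings of their source", {
  refs <- simulate_references(3, 4000, seed = 5)
  sim <- simulate_reads(refs, sim_config(n_reads = 300, read_length = 80,
                                         error_rate = 0, seed = 6))
  expect_equal(nchar(sim$reads$seq), rep(80L, 300))
  for (i in seq_len(300)) {
    src <- sim$truth$ref_id[i]
    win <- substr(refs$seq[refs$id == src], sim$truth$offset[i] + 1,
                  sim$truth$offset[i] + 80)
    expect_identical(sim$reads$seq[i], win)
  }
})

test_that("injected error counts follow the binomial model", {
  refs <- simulate_reference(20000, seed = 21)
  S <- 2000; L <- 100; e <- 0.05
  sim <- simulate_reads(refs, sim_config(n_reads = S, read_length = L,
                                         error_rate = e, seed = 22))
  edits <- sim$truth$n_sub + sim$truth$n_ins + sim$truth$n_del
  # mean per-read edits ~ L*e; total is Binomial(S*L, e), checked at 4 sigma
  tot <- sum(edits)
  expect_lt(abs(tot - S * L * e), 4 * sqrt(S * L * e * (1 - e)))
  expect_lt(abs(mean(edits) - 5.0), 0.3)
  # direct-count oracle: for substitution-only reads the number of
  # differing positions against the source window equals n_sub exactly
  subs_only <- which(sim$truth$n_del == 0 & sim$truth$n_ins == 0)[1:100]
  for (i in subs_only) {
    win <- substr(refs$seq, sim$truth$offset[i] + 1, sim$truth$offset[i] + L)
    mm <- sum(strsplit(sim$reads$seq[i], "")[[1]] != strsplit(win, "")[[1]])
    expect_identical(as.integer(mm), as.integer(sim$truth$n_sub[i]))
    expect_lte(utils::adist(sim$reads$seq[i], win)[1, 1], mm)
  }
})

test_that("error composition defaults to 0.9/0.05/0.05 S/I/D", {
  refs <- simulate_reference(50000, seed = 31)
  sim <- simulate_reads(refs, sim_config(n_reads = 4000, read_length = 100,
                                         error_rate = 0.05, seed = 32))
  tot <- c(sum(sim$truth$n_sub), sum(sim$truth$n_ins), sum(sim$truth$n_del))
  frac <- tot / sum(tot)
  expect_lt(abs(frac[1] - 0.9), 0.02)
  expect_lt(abs(frac[2] - 0.05), 0.02)
  expect_lt(abs(frac[3] - 0.05), 0.02)
})

test_that("mixture mode draws only from the stated source references", {
  refs <- simulate_references(15, 2000, seed = 41)
  sim <- simulate_reads(refs, sim_config(
    n_reads = 400, read_length = 100, seed = 42,
    source_refs = c("ref03", "ref11")))
  expect_setequal(unique(sim$truth$ref_id), c("ref03", "ref11"))
})

test_that("identical configurations give byte-identical FASTQ", {
  refs <- simulate_reference(5000, seed = 51)
  cfg <- sim_config(n_reads = 200, read_length = 90, error_rate = 0.01,
                    seed = 52)
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq(simulate_reads(refs, cfg)$reads, f1)
  write_fastq(simulate_reads(refs, cfg)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(file.size(f1), 0)
})

test_that("redundancy mode oversamples few sites and strand mode flips", {
  refs <- simulate_reference(8000, seed = 61)
  sim <- simulate_reads(refs, sim_config(n_reads = 1000, read_length = 60,
                                         seed = 62, n_source_sites = 20))
  expect_lte(length(unique(sim$truth$offset)), 20L)
  expect_lte(length(unique(sim$reads$seq)), 20L)
  simb <- simulate_reads(refs, sim_config(n_reads = 500, read_length = 60,
                                          seed = 63, strand = "both"))
  expect_setequal(unique(simb$truth$strand), c("+", "-"))
  minus <- which(simb$truth$strand == "-")[1]
  win <- substr(refs$seq, simb$truth$offset[minus] + 1,
                simb$truth$offset[minus] + 60)
  expect_identical(simb$reads$seq[minus], revcomp(win))
})
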