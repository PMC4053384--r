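test_that("FASTA parsing handles single, multi-line and multi-record files", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), fa)
  expect_equal(read_fasta(fa),
               data.frame(id = "a", seq = "ACGT", stringsAsFactors = FALSE))
  writeLines(c(">a", "AC", "GT", ">b", "TT"), fa)
  got <- read_fasta(fa)
  expect_equal(got$id, c("a", "b"))
  expect_equal(got$seq, c("ACGT", "TT"))
  writeLines(c(">a", "acgt"), fa)
  expect_equal(read_fasta(fa)$seq, "ACGT")
})

test_that("malformed FASTA is rejected with a line number", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines("ACGT", fa)
  expect_error(read_fasta(fa), "line 1")
  writeLines(c(">a", ">b", "ACGT"), fa)
  expect_error(read_fasta(fa), "line 1.*empty record")
})

test_that("FASTA writing round-trips exactly", {
  set.seed(401)
  refs <- data.frame(id = c("r1", "r2", "r3"),
                     seq = vapply(c(5L, 143L, 70L),
                                  function(n) random_dna(n), ""),
                     stringsAsFactors = FALSE)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(refs, fa)
  expect_equal(read_fasta(fa), refs)
})

test_that("FASTQ parsing enforces the seq/qual length contract", {
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r", "ACGT", "+", "IIII"), fq)
  expect_equal(read_fastq(fq),
               data.frame(id = "r", seq = "ACGT", qual = "IIII",
                          stringsAsFactors = FALSE))
  writeLines(c("@r", "ACGT", "+", "III"), fq)
  expect_error(read_fastq(fq), "FASTQ")
  file.create(fq2 <- withr::local_tempfile(fileext = ".fq"))
  expect_equal(nrow(read_fastq(fq2)), 0L)
})

test_that("2-bit encoding round-trips over random ACGT strings", {
  set.seed(402)
  for (i in 1:50) {
    s <- random_dna(sample(1:200, 1))
    expect_identical(decode_2na(encode_2na(s)), s)
  }
  expect_error(encode_2na("ACNT"), "non-ACGT")
  expect_error(encode_2na(""), "empty")
})

test_that("k-mer codes follow the A/C/G/T=0/1/2/3 big-endian convention", {
  expect_equal(kmer_code("ACGT", 0, 4), 27)       # 0*64 + 1*16 + 2*4 + 3
  expect_equal(kmer_code("AAAA", 0, 4), 0)
  expect_true(is.na(kmer_code("ACNT", 0, 4)))     # unindexable k-mer
  expect_equal(kmer_code("TACGT", 1, 4), 27)      # offset is 0-based
  expect_error(kmer_code("ACGT", 2, 4), "outside")
  expect_error(kmer_code(strrep("A", 40), 0, 30), "26")
})

test_that("integer order of k-mer codes equals lexicographic k-mer order", {
  set.seed(403)
  kmers <- replicate(40, random_dna(6))
  codes <- vapply(kmers, function(s) kmer_code(s, 0, 6), numeric(1))
  expect_identical(order(codes), order(kmers, method = "radix"))
})

test_that("reverse complement is correct and self-inverse", {
  expect_identical(revcomp("AACG"), "CGTT")
  expect_identical(revcomp("ACGTN"), "NACGT")
  set.seed(404)
  s <- random_dna(77)
  expect_identical(revcomp(revcomp(s)), s)
})

test_that("SAM output honours POS/CIGAR/FLAG conventions and validates", {
  set.seed(405)
  ref <- data.frame(id = "chr", seq = random_dna(400))
  fwd <- substr(ref$seq, 1, 50)           # perfect match at offset 0
  rc <- revcomp(substr(ref$seq, 101, 150))
  reads <- data.frame(id = c("m", "r", "u"),
                      seq = c(fwd, rc, paste(rep("ACGT", 13), collapse = "")),
                      qual = NA_character_, stringsAsFactors = FALSE)
  cfg <- pipeline_config(min_match = 20)
  res <- run_pipeline(ref, reads, cfg)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(res, sam)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  expect_length(body, 3L)
  f <- do.call(rbind, lapply(strsplit(body, "\t"), `[`, 1:11))
  rownames(f) <- f[, 1]
  expect_equal(unname(f["m", 2]), "0")
  expect_equal(unname(f["m", 4]), "1")    # 1-based POS
  expect_equal(unname(f["m", 6]), "50M")
  expect_equal(as.integer(f["r", 2]) %% 32 %/% 16, 1L)  # 0x10 set
  expect_equal(unname(f["r", 10]), revcomp(rc))  # SEQ reverse-complemented
  expect_equal(unname(f["u", 2]), "4")
  expect_equal(unname(f["u", 3]), "*")
  # external validator accepts the file
  expect_equal(system2("samtools", c("view", "-c", sam),
                       stdout = NULL, stderr = NULL), 0L)
})

test_that("count expansion emits one record per input read", {
  set.seed(406)
  ref <- data.frame(id = "chr", seq = random_dna(500))
  base <- substring(ref$seq, c(1, 51, 101), c(50, 100, 150))
  reads <- data.frame(id = sprintf("rd%02d", 1:9),
                      seq = rep(base, each = 3), qual = NA_character_)
  res <- run_pipeline(ref, reads, pipeline_config(min_match = 20))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(res, sam, expand_counts = TRUE)
  body <- grep("^@", readLines(sam), invert = TRUE, value = TRUE)
  expect_length(body, nrow(reads))
  write_sam(res, sam, expand_counts = FALSE)
  body <- grep("^@", readLines(sam), invert = TRUE, value = TRUE)
  expect_length(body, 3L)
  expect_true(all(grepl("XC:i:3", body)))
})
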