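# Independent oracles used across the suite. These never share code with
# the package's own alignment path.

DNA <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

mutate_subs <- function(seq, positions) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) v[p] <- sample(setdiff(DNA, v[p]), 1L)
  paste(v, collapse = "")
}

# full-matrix local Smith-Waterman score via Biostrings (affine gaps,
# gap of n costs gapOpening + n * gapExtension)
oracle_sw_score <- function(read, ref, match = 5, mismatch = -4,
                            gap_open = -12, gap_ext = -2,
                            type = "local") {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(ref), type = type,
    substitutionMatrix = mat, gapOpening = -gap_open, gapExtension = -gap_ext,
    scoreOnly = TRUE)
}

# tiny pure-R full-matrix local Gotoh, O(n*m); used as a second,
# library-independent oracle at small sizes
oracle_sw_tiny <- function(a, b, match = 5, mismatch = -4, open = -12,
                           ext = -2) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (t in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[t, j] <- max(E[t, j - 1] + ext, H[t, j - 1] + open + ext)
      F[t, j] <- max(F[t - 1, j] + ext, H[t - 1, j] + open + ext)
      s <- if (A[t - 1] == B[j - 1]) match else mismatch
      H[t, j] <- max(0, H[t - 1, j - 1] + s, E[t, j], F[t, j])
      if (H[t, j] > best) best <- H[t, j]
    }
  }
  best
}

# brute-force exact k-mer hits between read and ref as (diag, pos, roff)
oracle_kmer_hits <- function(ref, read, K) {
  G <- nchar(ref)
  L <- nchar(read)
  refk <- substring(ref, 1:(G - K + 1), K:G)
  out <- NULL
  for (roff in 0:(L - K)) {
    km <- substr(read, roff + 1, roff + K)
    pos <- which(refk == km) - 1L
    if (length(pos))
      out <- rbind(out, data.frame(pos = pos, roff = roff,
                                   diag = pos - roff))
  }
  out
}

# hash-map style dedup oracle: sorted unique sequences with counts
oracle_dedup <- function(seqs) {
  tab <- table(seqs)
  us <- sort(names(tab), method = "radix")
  list(seq = us, count = as.integer(tab[us]))
}

oracle_lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  i <- 0L
  while (i < n && substr(a, i + 1, i + 1) == substr(b, i + 1, i + 1))
    i <- i + 1L
  i
}
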