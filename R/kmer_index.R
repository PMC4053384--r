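# Direct-addressed k-mer index over the reference set. The 2-na code of a
# k-mer is its bucket address; a one-bit-per-code presence table is
# consulted before any bucket fetch, and buckets whose occupancy exceeds
# the over-expression threshold are masked (flagged, never deleted), which
# suppresses candidates from low-complexity / repeated regions.

#' Build the k-mer index of a reference set
#'
#' Indexes every `step`-th N-free position of every reference (complexity
#' linear in the cumulative reference size). Buckets with more than
#' `threshold` occurrences are marked over-expressed and contribute no
#' candidates at lookup time; the presence bit of a bucket reflects its
#' pre-masking occupancy, so a presence miss always means an empty bucket.
#'
#' @param references a reference set (see [as_reference_set()]).
#' @param k seed length, 1..14. Longer configured seeds are served by
#'   double lookup at query time (see [lookup_seeds()]).
#' @param threshold over-expression threshold T: maximum bucket occupancy
#'   before masking (default 50).
#' @param step index every `step`-th reference position (default 1).
#' @param min_entropy optional low-complexity reference masking: exclude
#'   seed starts in `entropy_window`-base tiles whose 2-mer Shannon entropy
#'   (bits) is below this value (0 disables; an interpretation, off by
#'   default).
#' @param entropy_window tile width for the entropy mask.
#' @return an object of class `kmer_index`.
#' @export
build_kmer_index <- function(references, k = 14L, threshold = 50L, step = 1L,
                             min_entropy = 0, entropy_window = 32L) {
  refs <- as_reference_set(references)
  ptr <- cpp_ki_build(refs$seq, refs$id, as.integer(k), as.integer(threshold),
                      as.integer(step), min_entropy,
                      as.integer(entropy_window))
  structure(list(ptr = ptr, k = as.integer(k),
                 threshold = as.integer(threshold), step = as.integer(step),
                 ref_ids = refs$id, ref_lengths = nchar(refs$seq)),
            class = "kmer_index")
}

#' Candidate discovery for one read
#'
#' Retrieves the read's k-mers sequentially, consults the presence bit
#' before any bucket fetch, skips masked (over-expressed) buckets, and
#' returns candidate positions de-duplicated on (reference, diagonal) with
#' the leftmost read offset and a per-diagonal seed count retained for
#' best-first ranking. When `seed_len > k` a candidate requires two exact
#' sub-k-mer matches at read offsets `roff` and `roff + (seed_len - k)` on
#' the same diagonal (double lookup, continuous coverage of the full
#' `seed_len` window).
#'
#' @param index a [build_kmer_index()] object.
#' @param read a read sequence (length >= `k`).
#' @param seed_len effective seed length in `[k, 2k]`; default `k`.
#' @return a list with `hits` (data.frame `ref` 1-based reference ordinal,
#'   `ref_id`, `pos` 0-based reference position, `read_offset`, `n_seeds`)
#'   and `counters` (offsets examined, presence-bit hits, bucket fetches,
#'   raw hits before diagonal de-duplication, masked skips).
#' @export
lookup_seeds <- function(index, read, seed_len = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  if (is.null(seed_len)) seed_len <- index$k
  res <- cpp_ki_lookup(index$ptr, read, as.integer(seed_len))
  hits <- data.frame(ref = res$ref + 1L,
                     ref_id = index$ref_ids[res$ref + 1L],
                     pos = res$pos, read_offset = res$read_offset,
                     n_seeds = res$n_seeds, stringsAsFactors = FALSE)
  list(hits = hits, counters = res$counters)
}

#' @rdname build_kmer_index
#' @param index a `kmer_index`.
#' @export
index_info <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  cpp_ki_info(index$ptr)
}

#' Inspect one bucket of the index
#'
#' @param index a `kmer_index`.
#' @param kmer a k-mer string of the index's seed length.
#' @return list with `ref`/`pos` entry vectors (0-based), the presence bit
#'   and the masked flag.
#' @export
index_bucket <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  cpp_ki_bucket(index$ptr, toupper(kmer))
}

#' Release the index's bulky arrays eagerly
#'
#' The direct-address table of a K=14 index is large; releasing it
#' explicitly avoids waiting for the garbage collector between runs.
#'
#' @param index a `kmer_index`.
#' @export
release_index <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  cpp_ki_release(index$ptr)
  invisible(index)
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- tryCatch(cpp_ki_info(x$ptr), error = function(e) NULL)
  cat("<kmer_index> K=", x$k, ", T=", x$threshold, ", step=", x$step,
      ", refs=", length(x$ref_ids), sep = "")
  if (!is.null(info))
    cat(", entries=", format(info$n_entries, big.mark = ","),
        ", masked buckets=", info$n_masked, sep = "")
  cat("\n")
  invisible(x)
}
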