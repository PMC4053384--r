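# Read non-redundification: a compressed prefix (Patricia) tree over the
# 4-letter alphabet collapses exact duplicate reads while counting them;
# the left-maze traversal emits the unique reads in lexicographic order
# (A < C < G < T, a prefix-terminal before its extensions) together with
# the cross-similarity coefficient of each read, i.e. the length of the
# longest common prefix with the previous read in sorted order.

#' Create an empty prefix tree
#'
#' @return an object of class `prefix_tree` backed by an external pointer.
#' @seealso [tree_insert()], [sorted_traversal()], [dedup_reads()]
#' @export
prefix_tree <- function() {
  structure(list(ptr = cpp_pt_new()), class = "prefix_tree")
}

#' Insert a read into a prefix tree
#'
#' Duplicate detection is exact string equality; a duplicate increments the
#' redundancy count of the existing terminal, a new sequence creates at
#' most one edge split.
#'
#' @param tree a [prefix_tree()].
#' @param seq an A/C/G/T string (apply the N policy upstream).
#' @param ordinal original read ordinal (1-based), stored at the terminal.
#' @return `"new"` or `"duplicate"`, invisibly modifying the tree in place.
#' @export
tree_insert <- function(tree, seq, ordinal = 1L) {
  stopifnot(inherits(tree, "prefix_tree"))
  if (cpp_pt_insert(tree$ptr, seq, as.integer(ordinal))) "new" else "duplicate"
}

#' Sorted traversal of a prefix tree
#'
#' Visits every node exactly once, always taking the left path first, and
#' returns the unique reads in exact lexicographic order with redundancy
#' counts and cross-similarity coefficients.
#'
#' @param tree a [prefix_tree()].
#' @return a `unique_read_set`: list with `seq`, `count`,
#'   `cross_similarity`, `ordinals` (per-unique list of original ordinals)
#'   and `map` (original ordinal -> unique ordinal).
#' @export
sorted_traversal <- function(tree) {
  stopifnot(inherits(tree, "prefix_tree"))
  res <- cpp_pt_traverse(tree$ptr)
  as_unique_read_set(res)
}

as_unique_read_set <- function(res) {
  n_in <- sum(lengths(res$ordinals))
  map <- integer(0)
  if (n_in > 0) {
    ords <- unlist(res$ordinals, use.names = FALSE)
    map <- integer(max(ords))
    map[ords] <- rep.int(seq_along(res$ordinals), lengths(res$ordinals))
  }
  structure(list(seq = res$seq, count = res$count,
                 cross_similarity = res$cross_similarity,
                 ordinals = res$ordinals, map = map),
            class = "unique_read_set")
}

#' @export
print.unique_read_set <- function(x, ...) {
  cat("<unique_read_set> ", length(x$seq), " unique reads, ",
      sum(x$count), " total\n", sep = "")
  invisible(x)
}

#' Non-redundify a set of reads
#'
#' Builds the prefix tree (optionally split into `4^partition_k` disjoint
#' prefix classes, each with its own tree — no joining step is needed since
#' the classes cannot overlap) and returns the sorted unique read set.
#'
#' @param seqs character vector of A/C/G/T reads.
#' @param partition_k split the read space into `4^partition_k` buckets by
#'   the 2-na code of the first `partition_k` bases (0 = single tree).
#' @return a `unique_read_set` (see [sorted_traversal()]).
#' @examples
#' u <- dedup_reads(c("AGAC", "AGACT", "AGAC"))
#' u$seq; u$count; u$cross_similarity
#' @export
dedup_reads <- function(seqs, partition_k = 0L) {
  seqs <- toupper(as.character(seqs))
  if (partition_k == 0L) {
    tr <- prefix_tree()
    if (length(seqs))
      cpp_pt_insert_many(tr$ptr, seqs, seq_along(seqs))
    return(sorted_traversal(tr))
  }
  codes <- partition_by_prefix(seqs, partition_k)
  pieces <- lapply(sort(unique(codes)), function(b) {
    idx <- which(codes == b)
    tr <- prefix_tree()
    cpp_pt_insert_many(tr$ptr, seqs[idx], idx)
    cpp_pt_traverse(tr$ptr)
  })
  res <- list(seq = unlist(lapply(pieces, `[[`, "seq")),
              count = unlist(lapply(pieces, `[[`, "count")),
              cross_similarity = unlist(lapply(pieces, `[[`, "cross_similarity")),
              ordinals = do.call(c, lapply(pieces, `[[`, "ordinals")))
  if (is.null(res$seq)) res <- list(seq = character(), count = integer(),
                                    cross_similarity = integer(),
                                    ordinals = list())
  # cross-similarity across bucket boundaries (first entry of each bucket)
  sizes <- vapply(pieces, function(p) length(p$seq), integer(1))
  firsts <- cumsum(c(1L, sizes[-length(sizes)]))[sizes > 0]
  firsts <- firsts[firsts > 1L]
  if (length(firsts))
    res$cross_similarity[firsts] <-
      cpp_lcp(res$seq[firsts - 1L], res$seq[firsts])
  if (length(res$seq)) res$cross_similarity[1L] <- 0L
  as_unique_read_set(res)
}

#' Partition reads into 4^k prefix classes
#'
#' A read goes to the bucket whose index is the 2-na code of its first `k`
#' bases; reads shorter than `k` are padded with `A` for bucket assignment
#' only, and `N` counts as `A`. Buckets are disjoint and cover all reads,
#' and concatenating per-bucket sorted outputs in bucket order reproduces
#' the global sorted order.
#'
#' @param seqs character vector of reads.
#' @param k prefix length (>= 0).
#' @return integer vector of 0-based bucket codes in `[0, 4^k)`.
#' @export
partition_by_prefix <- function(seqs, k) {
  k <- as.integer(k)
  stopifnot(k >= 0)
  if (k == 0L) return(rep.int(0L, length(seqs)))
  pfx <- toupper(substr(seqs, 1L, k))
  short <- nchar(pfx) < k
  pfx[short] <- paste0(pfx[short], strrep("A", k - nchar(pfx[short])))
  strtoi(chartr("ACGTN", "01230", pfx), base = 4L)
}
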