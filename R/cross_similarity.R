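# Explicit cross-similarity: consecutive reads in sorted order share a
# prefix of c bases, so the candidate outcomes of the previous unique read
# predict those of the next. Candidate positions where the previous read's
# extension failed with a margin larger than the maximum score swing the
# differing suffix could produce are skipped. The memo depth is 1 (the
# immediately preceding sorted read only), and the option is off by
# default: it is not recommended for references distant from the sample.

# extension-stage scoring constants (match +1 / mismatch -1)
EXT_MATCH_SCORE <- 1L
EXT_MISMATCH_SCORE <- -1L

#' Candidate memo of the previous sorted read
#'
#' @param ref 0- or 1-based reference ordinals of the previous read's
#'   extended candidates (any consistent convention; the filter only
#'   matches keys).
#' @param diag candidate diagonals (`pos - read_offset`).
#' @param failed logical: did the extension fail at this candidate.
#' @param margin extension-score shortfall of failed candidates (>= 0).
#' @return an object of class `candidate_memo`.
#' @export
candidate_memo <- function(ref = integer(), diag = integer(),
                           failed = logical(), margin = numeric()) {
  stopifnot(length(ref) == length(diag), length(ref) == length(failed),
            length(ref) == length(margin))
  if (any(failed & margin < 0)) stop("fail margins must be >= 0")
  structure(list(ref = ref, diag = diag, failed = failed, margin = margin),
            class = "candidate_memo")
}

#' Cross-similarity candidate filtering
#'
#' Skips a candidate hit iff the previous (sorted, prefix-similar) read
#' failed extension at the same (reference, diagonal) with a margin larger
#' than the maximum score swing achievable by the differing suffix:
#' `margin > (L - c) * (match - mismatch) * margin_factor` under the
#' extension-stage scores (+1/-1). With `margin_factor = Inf` nothing is
#' ever skipped (equivalent to disabling the optimization).
#'
#' @param hits data.frame of candidate hits with columns `ref`, `pos`,
#'   `read_offset` (as returned by [lookup_seeds()]).
#' @param memo a [candidate_memo()] for the immediately preceding sorted
#'   read, or `NULL` (nothing skipped).
#' @param c cross-similarity coefficient: shared prefix length with the
#'   previous sorted read.
#' @param L current read length.
#' @param margin_factor safety factor on the skip bound (default 1).
#' @return `hits` with the skipped rows removed; the number skipped is in
#'   `attr(, "n_skipped")`.
#' @export
filter_candidates <- function(hits, memo, c, L, margin_factor = 1) {
  if (is.null(memo) || nrow(hits) == 0L || is.infinite(margin_factor)) {
    attr(hits, "n_skipped") <- 0L
    return(hits)
  }
  stopifnot(inherits(memo, "candidate_memo"))
  bound <- (L - c) * (EXT_MATCH_SCORE - EXT_MISMATCH_SCORE) * margin_factor
  bad <- memo$failed & memo$margin > bound
  if (!any(bad)) {
    attr(hits, "n_skipped") <- 0L
    return(hits)
  }
  keys <- paste(hits$ref, hits$pos - hits$read_offset)
  badkeys <- paste(memo$ref[bad], memo$diag[bad])
  drop <- keys %in% badkeys
  out <- hits[!drop, , drop = FALSE]
  attr(out, "n_skipped") <- sum(drop)
  out
}
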