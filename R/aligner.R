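# Optimal alignment on the bracketed frame: Smith-Waterman restricted to a
# floating, variable-width diagonal band. The band re-centers each read
# row on the column of the previous row's maximum, cells that provably
# cannot reach the reporting threshold are pruned ("holes"), and only the
# ~(2w+1) x L live band is stored (linearized), never the full L x G
# matrix.

#' Additive scoring parameters
#'
#' A gap of n bases costs `gap_open + n * gap_extend` (affine; set
#' `gap_open = 0` for pure linear gaps). Defaults: match +5, mismatch -4,
#' gap open -12, gap extend -2.
#'
#' @param match per-base match benefit (> 0).
#' @param mismatch per-base mismatch cost (<= 0).
#' @param gap_open gap opening cost (<= 0).
#' @param gap_extend per-base gap extension cost (<= 0).
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(match = 5L, mismatch = -4L, gap_open = -12L,
                           gap_extend = -2L) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_params")
}

#' Floating-band optimal alignment
#'
#' Runs the local (Smith-Waterman) recurrence row by row over the bracketed
#' read range, restricted per row to a band of half-width `w` centered on
#' the running best-scoring column (the floating center, moving at most
#' +/- `w` per row). With `prune = TRUE`, cells whose admissible score
#' upper bound cannot reach the reporting threshold are excluded from
#' computation and storage. The reporting threshold combines a minimal
#' score (`ceiling(min_match_len * (match * (1-a) + mismatch * a))` with
#' `a = mismatch_pct/100`), the minimal aligned read length, and the
#' mismatch+indel fraction.
#'
#' @param read,reference sequences.
#' @param bracket integer vector `c(read_start, read_end, ref_start,
#'   ref_end)`, 0-based half-open, from [fuzzy_extend()].
#' @param scoring a [scoring_params()].
#' @param w band half-width (default 8).
#' @param min_match_len minimal aligned read length to report (default 36).
#' @param mismatch_pct maximal percent of mismatch+indel columns
#'   (default 15).
#' @param prune enable score-bound cell pruning (default TRUE; disabling it
#'   gives plain banded SW with zero holes and identical results).
#' @param mode `"local"` (Smith-Waterman, default) or `"global"`
#'   (Needleman-Wunsch within the bracket, behind this flag).
#' @param float_band let the band center follow the highest-scoring path
#'   (default) instead of the fixed initial diagonal.
#' @param center0 initial band center: the column (0-based offset within
#'   the bracket's reference range) the alignment is expected to start on.
#'   0 when the bracket is exactly the extension frame; when the bracket
#'   carries slack, the offset of the extension frame inside it.
#' @param return_failed return the sub-threshold result (with diagnostics)
#'   instead of `NULL`.
#' @return an object of class `hex_alignment` (trajectory `ops` over
#'   M/X/I/D, `cigar`, 0-based half-open coordinates, `score`, tallies,
#'   band diagnostics), or `NULL` when no alignment meets the thresholds.
#' @examples
#' r <- "ACGTACGTAC"
#' band_align(r, r, c(0, 10, 0, 10), min_match_len = 5)
#' @export
band_align <- function(read, reference, bracket, scoring = scoring_params(),
                       w = 8L, min_match_len = 36L, mismatch_pct = 15,
                       prune = TRUE, mode = c("local", "global"),
                       float_band = TRUE, center0 = 0L,
                       return_failed = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(scoring, "scoring_params"), length(bracket) == 4L)
  res <- cpp_band_align(read, reference,
                        as.integer(bracket[1]), as.integer(bracket[2]),
                        as.integer(bracket[3]), as.integer(bracket[4]),
                        scoring$match, scoring$mismatch, scoring$gap_open,
                        scoring$gap_extend, as.integer(w), prune,
                        as.integer(min_match_len), mismatch_pct,
                        mode == "global", float_band, as.integer(center0))
  if (!isTRUE(res$passed) && !return_failed) return(NULL)
  structure(res, class = "hex_alignment")
}

#' Admissible score upper bound of a band cell
#'
#' Bounds the best total score attainable by any alignment passing through
#' a cell with accumulated path score `path_score` and `remaining` read
#' bases left. In local mode the completion never has to return to a
#' particular diagonal, so the bound is `path_score + remaining * match`;
#' in global mode a cell `distance` columns off the target diagonal must
#' additionally pay the forced gap schedule `gap_open + distance *
#' gap_extend`. The bound is admissible: never less than the true best
#' completion through the cell, which is what makes pruning score-safe.
#'
#' @param path_score accumulated score at the cell.
#' @param remaining read bases not yet consumed.
#' @param distance distance (in columns) from the band center.
#' @param scoring a [scoring_params()].
#' @param global use the global-mode schedule including the distance term.
#' @return integer upper bound.
#' @export
score_upper_bound <- function(path_score, remaining, distance = 0L,
                              scoring = scoring_params(), global = FALSE) {
  stopifnot(distance >= 0, remaining >= 0)
  b <- path_score + remaining * scoring$match
  if (global && distance > 0)
    b <- b + scoring$gap_open + distance * scoring$gap_extend
  b
}

#' @export
print.hex_alignment <- function(x, ...) {
  cat("<hex_alignment> score=", x$score,
      "  read[", x$read_start, ",", x$read_end, ") ref[", x$ref_start, ",",
      x$ref_end, ")  ", x$cigar,
      "  (", x$n_match, "=, ", x$n_mismatch, "X, ", x$n_ins, "I, ",
      x$n_del, "D)\n", sep = "")
  invisible(x)
}
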