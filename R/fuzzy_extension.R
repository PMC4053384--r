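# Cheap bidirectional extension of exact seed matches. The extension runs
# a small banded integer DP in a floating window around the seed diagonal,
# stops when the trailing-window mismatch density exceeds the allowance,
# and both filters accidental k-mer hits and brackets the frame for the
# optimal aligner. Thresholds are applied with a +1 mismatch slack so the
# expensive stage, not the filter, makes final calls.

#' Extension stage parameters
#'
#' @param min_len_pct minimal extension length as a percent of the read
#'   length (default 75).
#' @param mismatch_pct mismatch allowance percent during extension
#'   (default 15); also the trailing-window density bound.
#' @param window floating-window half-width of the extension front
#'   (allowed indel excursion, default 4).
#' @param density_window trailing window, in front rows, over which the
#'   mismatch density stop rule is evaluated (default 32).
#' @return an object of class `extension_params`.
#' @export
extension_params <- function(min_len_pct = 75, mismatch_pct = 15,
                             window = 4L, density_window = 32L) {
  stopifnot(min_len_pct >= 0, min_len_pct <= 100,
            mismatch_pct >= 0, mismatch_pct <= 100,
            window >= 1, density_window >= 1)
  structure(list(min_len_pct = min_len_pct, mismatch_pct = mismatch_pct,
                 window = as.integer(window),
                 density_window = as.integer(density_window)),
            class = "extension_params")
}

#' Fuzzy extension of a seed hit
#'
#' Extends an exact seed match bidirectionally with integer scoring
#' (match +1, mismatch -1, gap open -2, gap extend -1). The result passes
#' when the extended length reaches `min_len_pct` of the read length and
#' the mismatch+indel density stays within `mismatch_pct` (+1 slack);
#' failed results carry a non-negative score `margin` (shortfall against
#' the minimal passing extension score) used by the cross-similarity
#' candidate filter.
#'
#' @param read the read sequence.
#' @param reference the reference sequence the seed hit points into.
#' @param seed_hit a list with `read_offset`, `pos` (both 0-based) and
#'   `seed_len`, e.g. one row of [lookup_seeds()] hits.
#' @param params an [extension_params()].
#' @return an `extension_result`: `passed`, the bracket
#'   (`read_start`, `read_end`, `ref_start`, `ref_end`; 0-based half-open,
#'   always containing the seed), `score`, operation tallies and `margin`
#'   (-1 when passed).
#' @export
fuzzy_extend <- function(read, reference, seed_hit,
                         params = extension_params()) {
  stopifnot(inherits(params, "extension_params"))
  res <- cpp_fuzzy_extend(read, reference,
                          as.integer(seed_hit$read_offset),
                          as.integer(seed_hit$pos),
                          as.integer(seed_hit$seed_len),
                          params$min_len_pct, params$mismatch_pct,
                          params$window, params$density_window)
  structure(res, class = "extension_result")
}

#' @export
print.extension_result <- function(x, ...) {
  cat("<extension_result> ", if (x$passed) "PASS" else "fail",
      "  score=", x$score,
      "  read[", x$read_start, ",", x$read_end, ") ref[",
      x$ref_start, ",", x$ref_end, ")",
      "  mm=", x$n_mismatch, " ins=", x$n_ins, " del=", x$n_del,
      if (!x$passed) paste0("  margin=", x$margin), "\n", sep = "")
  invisible(x)
}
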