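# Full alignment workflow: non-redundify -> sort -> index -> lookup ->
# fuzzy extension -> floating-band optimal alignment -> report. Every
# unique read is aligned once and the result expanded by its redundancy
# count; the percent-unaligned statistic is computed over the original
# (redundant) read counts.

#' Pipeline configuration
#'
#' Defaults follow the production parameter set: seed length 14, minimum
#' match length 36, 15 percent mismatches allowed, extension minimal
#' length 75 percent with 15 percent mismatch allowance, first-best
#' reporting.
#'
#' @param k seed k-mer length (default 14; values in 15..28 are served by
#'   double lookup over an index of half the seed length).
#' @param min_match minimal aligned read length to report (default 36).
#' @param mismatch_pct maximal percent of mismatch+indel columns in a
#'   reported alignment (default 15).
#' @param ext_min_pct,ext_mismatch_pct,ext_window,ext_density_window
#'   extension-stage parameters, see [extension_params()].
#' @param overexpression_threshold mask k-mer buckets with more reference
#'   occurrences than this (default 50).
#' @param seed_step index every `seed_step`-th reference position.
#' @param band_width band half-width w of the optimal aligner (default 8).
#' @param candidate_cap at most this many candidate diagonals are extended
#'   per read and strand, best-first by seed count (default 200).
#' @param prune enable score-bound cell pruning in the optimal aligner.
#' @param cross_similarity enable explicit cross-similarity candidate
#'   skipping (off by default; not recommended for references distant from
#'   the sample).
#' @param cs_margin margin factor of the cross-similarity skip rule.
#' @param strand `"both"` (align read and reverse complement, keep the
#'   better score; default) or `"forward"`.
#' @param partition_k split the dedup tree into `4^partition_k` prefix
#'   classes (0 = single tree).
#' @param match,mismatch,gap_open,gap_extend scoring parameters of the
#'   optimal aligner, see [scoring_params()].
#' @param max_n_frac drop reads with more than this fraction of N bases
#'   (default 0.10); dropped reads count as unaligned.
#' @param read_min_entropy optional low-complexity read filter: drop reads
#'   whose 2-mer Shannon entropy (bits) is below this (0 disables).
#' @param ref_min_entropy optional low-complexity reference masking passed
#'   to [build_kmer_index()] (0 disables).
#' @param report `"best"` (first best alignment per read, default) or
#'   `"all"` (additionally collect every passing candidate alignment).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 14L, min_match = 36L, mismatch_pct = 15,
                            ext_min_pct = 75, ext_mismatch_pct = 15,
                            ext_window = 4L, ext_density_window = 32L,
                            overexpression_threshold = 50L, seed_step = 1L,
                            band_width = 8L, candidate_cap = 200L,
                            prune = TRUE, cross_similarity = FALSE,
                            cs_margin = 1, strand = c("both", "forward"),
                            partition_k = 0L, match = 5L, mismatch = -4L,
                            gap_open = -12L, gap_extend = -2L,
                            max_n_frac = 0.10, read_min_entropy = 0,
                            ref_min_entropy = 0,
                            report = c("best", "all")) {
  strand <- match.arg(strand)
  report <- match.arg(report)
  stopifnot(k >= 1, k <= 28, min_match >= 1, mismatch_pct >= 0,
            mismatch_pct <= 100, band_width >= 1, candidate_cap >= 1,
            max_n_frac >= 0, max_n_frac <= 1, cs_margin >= 0)
  structure(list(k = as.integer(k), min_match = as.integer(min_match),
                 mismatch_pct = mismatch_pct, ext_min_pct = ext_min_pct,
                 ext_mismatch_pct = ext_mismatch_pct,
                 ext_window = as.integer(ext_window),
                 ext_density_window = as.integer(ext_density_window),
                 overexpression_threshold = as.integer(overexpression_threshold),
                 seed_step = as.integer(seed_step),
                 band_width = as.integer(band_width),
                 candidate_cap = as.integer(candidate_cap), prune = prune,
                 cross_similarity = cross_similarity, cs_margin = cs_margin,
                 strand = strand, partition_k = as.integer(partition_k),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 max_n_frac = max_n_frac,
                 read_min_entropy = read_min_entropy,
                 ref_min_entropy = ref_min_entropy, report = report),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# 2-mer Shannon entropy (bits) of each sequence
seq_entropy2 <- function(seqs) {
  vapply(seqs, function(s) {
    if (nchar(s) < 2) return(0)
    d <- substring(s, 1:(nchar(s) - 1), 2:nchar(s))
    p <- table(d) / length(d)
    -sum(p * log2(p))
  }, numeric(1), USE.NAMES = FALSE)
}

# vector form of the cross-similarity skip rule (see filter_candidates)
cs_keep_idx <- function(refv, diagv, memo, c, L, margin_factor) {
  if (is.null(memo) || is.infinite(margin_factor)) return(seq_along(refv))
  bound <- (L - c) * (EXT_MATCH_SCORE - EXT_MISMATCH_SCORE) * margin_factor
  bad <- memo$failed & memo$margin > bound
  if (!any(bad)) return(seq_along(refv))
  badkeys <- paste(memo$ref[bad], memo$diag[bad])
  which(!(paste(refv, diagv) %in% badkeys))
}

#' Run the full alignment pipeline
#'
#' Executes dedup -> sort -> index -> lookup -> extend -> optimal align ->
#' report. Alignments are computed once per unique read and expanded by
#' redundancy count; ties in score are resolved to the first candidate
#' encountered in lookup order (deterministic first-best reporting). The
#' whole run is deterministic: fixed config and inputs give byte-identical
#' SAM output.
#'
#' @param references a reference set (see [as_reference_set()]).
#' @param reads a read set (see [as_read_set()]), e.g. from [read_fastq()]
#'   or [simulate_reads()].
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress.
#' @return an object of class `hexalign_result`: `alignments` (one row per
#'   unique read), `read_map` (original read -> unique ordinal, NA for
#'   dropped reads), `reads`, `references` (ids and lengths), `summary`,
#'   `counters`, `timings`, `config`, and `secondary` when
#'   `report = "all"`.
#' @export
run_pipeline <- function(references, reads, config = pipeline_config(),
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  tick <- function() proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(...)
  timings <- c()
  t0 <- tick()

  refs <- as_reference_set(references)
  rds <- as_read_set(reads)
  S <- nrow(rds)

  # ---- read filtering (N policy, optional low-complexity filter) ----
  keep <- rep(TRUE, S)
  if (S > 0) {
    nfrac <- 1 - nchar(gsub("[^ACGT]", "", rds$seq)) / nchar(rds$seq)
    keep <- nfrac <= config$max_n_frac
  }
  n_dropped_n <- sum(!keep)
  n_dropped_lc <- 0L
  if (config$read_min_entropy > 0 && any(keep)) {
    lc <- seq_entropy2(rds$seq[keep]) < config$read_min_entropy
    n_dropped_lc <- sum(lc)
    keep[which(keep)[lc]] <- FALSE
  }
  kept <- which(keep)
  timings["filter"] <- tick() - t0
  say("filter: ", length(kept), "/", S, " reads kept")

  # ---- non-redundification + sort ----
  t0 <- tick()
  keptseq <- rds$seq[kept]
  pure <- !grepl("[^ACGT]", keptseq)
  u <- dedup_reads(keptseq[pure], config$partition_k)
  U0 <- length(u$seq)
  idx_pure <- which(pure)
  idx_n <- which(!pure)
  useq <- c(u$seq, keptseq[idx_n])
  ucount <- c(u$count, rep(1L, length(idx_n)))
  ucs <- c(u$cross_similarity, rep(0L, length(idx_n)))
  map_kept <- integer(length(keptseq))
  if (length(idx_pure)) map_kept[idx_pure] <- u$map
  if (length(idx_n)) map_kept[idx_n] <- U0 + seq_along(idx_n)
  read_map <- rep(NA_integer_, S)
  read_map[kept] <- map_kept
  rep_read <- c(
    if (U0) kept[idx_pure[vapply(u$ordinals, min, integer(1))]] else integer(),
    kept[idx_n])
  U <- length(useq)
  timings["dedup"] <- tick() - t0
  say("dedup: ", U, " unique reads from ", length(kept))

  # ---- reference k-mer index (recompiled per run) ----
  t0 <- tick()
  index_k <- if (config$k > 14L) as.integer(ceiling(config$k / 2)) else config$k
  idx <- build_kmer_index(refs, k = index_k,
                          threshold = config$overexpression_threshold,
                          step = config$seed_step,
                          min_entropy = config$ref_min_entropy)
  on.exit(release_index(idx), add = TRUE)
  timings["index"] <- tick() - t0
  say("index: K=", index_k, ", ", index_info(idx)$n_entries, " entries")

  # ---- per-unique-read alignment ----
  t0 <- tick()
  a_ref <- a_pos <- a_score <- a_rs <- a_re <-
    a_nm <- a_nx <- a_ni <- a_nd <- rep(NA_integer_, U)
  a_strand <- a_cigar <- rep(NA_character_, U)
  a_reason <- rep(NA_character_, U)
  strands <- if (config$strand == "both") c("+", "-") else "+"
  memo_prev <- stats::setNames(vector("list", length(strands)), strands)
  band_calls <- 0L
  cs_skipped <- 0L
  lookup_offsets <- 0
  bloom_hits <- 0
  bucket_fetches <- 0
  secondary <- if (config$report == "all") vector("list", U) else NULL
  slack_r <- config$band_width
  slack_q <- 2L * config$band_width

  for (uu in seq_len(U)) {
    s0 <- useq[uu]
    L <- nchar(s0)
    best <- NULL
    memo_cur <- stats::setNames(vector("list", length(strands)), strands)
    any_hits <- FALSE
    any_masked <- FALSE
    any_ext_pass <- FALSE
    sec <- NULL
    for (si in seq_along(strands)) {
      st <- strands[si]
      if (L < config$k) next
      s <- if (st == "-") revcomp(s0) else s0
      lk <- cpp_ki_lookup(idx$ptr, s, config$k)
      lookup_offsets <- lookup_offsets + lk$counters$n_offsets
      bloom_hits <- bloom_hits + lk$counters$bloom_hits
      bucket_fetches <- bucket_fetches + lk$counters$bucket_fetches
      if (lk$counters$masked_skips > 0) any_masked <- TRUE
      nh <- length(lk$ref)
      if (nh == 0L) next
      refv <- lk$ref
      posv <- lk$pos
      roffv <- lk$read_offset
      nseedv <- lk$n_seeds
      sel <- seq_len(nh)
      if (config$cross_similarity) {
        sel <- cs_keep_idx(refv, posv - roffv, memo_prev[[st]], ucs[uu], L,
                           config$cs_margin)
        cs_skipped <- cs_skipped + (nh - length(sel))
      }
      if (length(sel) == 0L) { memo_cur[[st]] <- NULL; next }
      any_hits <- TRUE
      ord <- sel[order(-nseedv[sel])]
      if (length(ord) > config$candidate_cap)
        ord <- ord[seq_len(config$candidate_cap)]
      ext <- cpp_fuzzy_extend_batch(s, refs$seq, refv[ord], posv[ord],
                                    roffv[ord], config$k, config$ext_min_pct,
                                    config$ext_mismatch_pct,
                                    config$ext_window,
                                    config$ext_density_window)
      memo_cur[[st]] <- list(ref = refv[ord], diag = posv[ord] - roffv[ord],
                             failed = ext[, "passed"] == 0,
                             margin = ext[, "margin"])
      passing <- which(ext[, "passed"] == 1)
      if (length(passing)) any_ext_pass <- TRUE
      for (i in passing) {
        ci <- ord[i]
        G <- nchar(refs$seq[refv[ci] + 1L])
        br <- c(max(0L, ext[i, "read_start"] - slack_r),
                min(L, ext[i, "read_end"] + slack_r),
                max(0L, ext[i, "ref_start"] - slack_q),
                min(G, ext[i, "ref_end"] + slack_q))
        band_calls <- band_calls + 1L
        # expected start diagonal of the extension frame within the
        # slack-enlarged bracket
        center0 <- (ext[i, "ref_start"] - br[3]) - (ext[i, "read_start"] - br[1])
        al <- cpp_band_align(s, refs$seq[refv[ci] + 1L], br[1], br[2],
                             br[3], br[4], config$match, config$mismatch,
                             config$gap_open, config$gap_extend,
                             config$band_width, config$prune,
                             config$min_match, config$mismatch_pct,
                             FALSE, TRUE, center0)
        if (!isTRUE(al$passed)) next
        if (!is.null(secondary))
          sec <- rbind(sec, data.frame(
            unique_id = uu, ref = refv[ci] + 1L, pos = al$ref_start,
            strand = st, score = al$score, cigar = al$cigar,
            stringsAsFactors = FALSE))
        replace <- is.null(best) || al$score > best$score ||
          (al$score == best$score && si == best$si && ci < best$ci)
        if (replace)
          best <- list(score = al$score, ref = refv[ci], pos = al$ref_start,
                       st = st, si = si, ci = ci, cigar = al$cigar,
                       rs = al$read_start, re = al$read_end,
                       nm = al$n_match, nx = al$n_mismatch, ni = al$n_ins,
                       nd = al$n_del)
      }
    }
    memo_prev <- memo_cur
    if (!is.null(secondary)) secondary[[uu]] <- sec
    if (!is.null(best)) {
      a_ref[uu] <- best$ref + 1L
      a_pos[uu] <- best$pos
      a_strand[uu] <- best$st
      a_score[uu] <- best$score
      a_cigar[uu] <- best$cigar
      a_rs[uu] <- best$rs
      a_re[uu] <- best$re
      a_nm[uu] <- best$nm
      a_nx[uu] <- best$nx
      a_ni[uu] <- best$ni
      a_nd[uu] <- best$nd
    } else {
      a_reason[uu] <-
        if (!any_hits && any_masked) "overexpressed_seeds"
        else if (!any_hits) "no_seed_hits"
        else if (!any_ext_pass) "extension_failed"
        else "below_threshold"
    }
  }
  timings["align"] <- tick() - t0
  say("align: ", sum(!is.na(a_ref)), "/", U, " unique reads aligned")

  # ---- expansion + summary ----
  aligned_u <- !is.na(a_ref)
  aligned_reads <- sum(ucount[aligned_u])
  unaligned_reads <- S - aligned_reads
  per_ref <- integer(nrow(refs))
  if (any(aligned_u))
    for (r in unique(a_ref[aligned_u]))
      per_ref[r] <- sum(ucount[aligned_u & a_ref == r])
  alignments <- data.frame(
    unique_id = seq_len(U), seq = useq, count = ucount,
    cross_similarity = ucs, rep_read = rep_read, aligned = aligned_u,
    ref = a_ref, ref_id = ifelse(is.na(a_ref), NA, refs$id[a_ref]),
    pos = a_pos, strand = a_strand, score = a_score, cigar = a_cigar,
    read_start = a_rs, read_end = a_re, n_match = a_nm, n_mismatch = a_nx,
    n_ins = a_ni, n_del = a_nd, reason = a_reason, stringsAsFactors = FALSE)
  res <- structure(list(
    alignments = alignments,
    read_map = read_map,
    reads = rds,
    references = data.frame(id = refs$id, length = nchar(refs$seq),
                            stringsAsFactors = FALSE),
    summary = list(
      total_reads = S, dropped_high_n = n_dropped_n,
      dropped_low_complexity = n_dropped_lc, unique_reads = U,
      aligned_reads = aligned_reads, unaligned_reads = unaligned_reads,
      pct_unaligned = if (S > 0) 100 * unaligned_reads / S else 0,
      per_reference = data.frame(ref_id = refs$id, aligned_reads = per_ref,
                                 stringsAsFactors = FALSE)),
    counters = list(band_align_calls = band_calls,
                    cross_similarity_skipped = cs_skipped,
                    lookup_offsets = lookup_offsets,
                    bloom_hits = bloom_hits,
                    bucket_fetches = bucket_fetches),
    timings = timings,
    config = config), class = "hexalign_result")
  if (!is.null(secondary)) res$secondary <- do.call(rbind, secondary)
  res
}

#' @export
print.hexalign_result <- function(x, ...) {
  s <- x$summary
  cat("<hexalign_result>\n")
  cat(sprintf("  reads:            %d (%d unique; %d dropped)\n",
              s$total_reads, s$unique_reads,
              s$dropped_high_n + s$dropped_low_complexity))
  cat(sprintf("  aligned:          %d\n", s$aligned_reads))
  cat(sprintf("  percent unaligned: %.4f\n", s$pct_unaligned))
  if (nrow(x$references) <= 20) {
    pr <- s$per_reference
    for (i in seq_len(nrow(pr)))
      if (pr$aligned_reads[i] > 0)
        cat(sprintf("    %-12s %d\n", pr$ref_id[i], pr$aligned_reads[i]))
  }
  cat("  timings (s):       ",
      paste(sprintf("%s=%.2f", names(x$timings), x$timings),
            collapse = " "), "\n")
  invisible(x)
}

#' Evaluate alignments against a simulator truth table
#'
#' @param result a [run_pipeline()] result for reads generated by
#'   [simulate_reads()].
#' @param truth the simulator truth table (`read_id`, `ref_id`, `offset`,
#'   `strand`); must match the read set exactly.
#' @param pos_tol positional tolerance in bases (default 5).
#' @return a list: `fraction_unaligned` over all reads; among aligned
#'   reads, `fraction_correct_ref` and `fraction_correct_pos` (correct
#'   reference, strand and position within `pos_tol`).
#' @export
evaluate_against_truth <- function(result, truth, pos_tol = 5L) {
  stopifnot(inherits(result, "hexalign_result"),
            all(c("read_id", "ref_id", "offset", "strand") %in% names(truth)))
  ids <- result$reads$id
  if (anyDuplicated(truth$read_id) || length(ids) != nrow(truth) ||
      !all(ids %in% truth$read_id))
    stop("truth table does not match the read set (ids differ)")
  tr <- truth[match(ids, truth$read_id), ]
  u <- result$read_map
  A <- result$alignments
  aligned <- !is.na(u) & A$aligned[ifelse(is.na(u), 1L, u)]
  if (!any(aligned))
    return(list(fraction_unaligned = 1, fraction_correct_ref = NA_real_,
                fraction_correct_pos = NA_real_))
  ua <- u[aligned]
  corr_ref <- A$ref_id[ua] == tr$ref_id[aligned]
  corr_pos <- corr_ref & A$strand[ua] == tr$strand[aligned] &
    abs(A$pos[ua] - tr$offset[aligned]) <= pos_tol
  list(fraction_unaligned = 1 - mean(aligned),
       fraction_correct_ref = mean(corr_ref),
       fraction_correct_pos = mean(corr_pos))
}
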