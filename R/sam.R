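# SAM v1.6 output. Internal coordinates are 0-based half-open; SAM POS is
# 1-based. Reverse-strand alignments are computed on the reverse
# complement of the read against the forward reference, so SEQ is emitted
# reverse-complemented with FLAG 0x10 and the CIGAR applies as computed.

str_reverse <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                              collapse = ""), character(1), USE.NAMES = FALSE)
}

#' Write alignments as SAM
#'
#' Emits a valid SAM v1.6 file with `@HD`/`@SQ` headers. With
#' `expand_counts = TRUE` (default) each redundant copy of a de-duplicated
#' read gets its own record under its original id; with `FALSE` one record
#' is emitted per unique read (under the id of its first original copy)
#' with the redundancy count in the `XC:i` tag. Unaligned reads are
#' emitted with the unmapped flag. Output is deterministic.
#'
#' @param result a [run_pipeline()] result.
#' @param path output file path.
#' @param expand_counts emit one record per original read (default) or one
#'   per unique read with an `XC:i` count tag.
#' @return `path`, invisibly.
#' @export
write_sam <- function(result, path, expand_counts = TRUE) {
  stopifnot(inherits(result, "hexalign_result"))
  A <- result$alignments
  refs <- result$references
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", refs$id, refs$length),
              paste0("@PG\tID:hexalign\tPN:hexalign\tVN:",
                     as.character(utils::packageVersion("hexalign"))))

  if (expand_counts) {
    ids <- result$reads$id
    seqs <- result$reads$seq
    quals <- result$reads$qual
    u <- result$read_map
    n <- length(ids)
    sel <- ifelse(is.na(u), NA_integer_, u)
  } else {
    sel <- A$unique_id
    ids <- result$reads$id[A$rep_read]
    seqs <- A$seq
    quals <- result$reads$qual[A$rep_read]
    n <- nrow(A)
  }

  aligned <- !is.na(sel) & A$aligned[ifelse(is.na(sel), 1L, sel)]
  idx <- ifelse(aligned, sel, 1L)
  minus <- aligned & A$strand[idx] == "-"

  outseq <- seqs
  outqual <- ifelse(is.na(quals), "*", quals)
  if (any(minus)) {
    outseq[minus] <- revcomp(seqs[minus])
    rq <- outqual[minus]
    rq[rq != "*"] <- str_reverse(rq[rq != "*"])
    outqual[minus] <- rq
  }

  flag <- ifelse(aligned, ifelse(minus, 16L, 0L), 4L)
  rname <- ifelse(aligned, A$ref_id[idx], "*")
  pos <- ifelse(aligned, A$pos[idx] + 1L, 0L)
  mapq <- ifelse(aligned, 255L, 0L)
  lead <- ifelse(aligned, A$read_start[idx], 0L)
  trail <- ifelse(aligned, nchar(outseq) - A$read_end[idx], 0L)
  cigar <- ifelse(aligned,
                  paste0(ifelse(lead > 0, paste0(lead, "S"), ""),
                         A$cigar[idx],
                         ifelse(trail > 0, paste0(trail, "S"), "")),
                  "*")
  nm <- A$n_mismatch[idx] + A$n_ins[idx] + A$n_del[idx]
  tags <- ifelse(aligned,
                 paste0("NM:i:", nm, "\tAS:i:", A$score[idx]), "")
  if (!expand_counts)
    tags <- paste0(tags, ifelse(nzchar(tags), "\t", ""),
                   "XC:i:", A$count[sel])
  recs <- paste(ids, flag, rname, pos, mapq, cigar, "*", 0L, 0L,
                outseq, outqual, sep = "\t")
  recs <- ifelse(nzchar(tags), paste(recs, tags, sep = "\t"), recs)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, recs), con)
  invisible(path)
}
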