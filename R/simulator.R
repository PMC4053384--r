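# Synthetic reference and read generation for sensitivity experiments.
# Artificial read sets at 0% / 1% / 5% per-base error emulate increasing
# divergence between sample and reference; a truth table records the
# provenance of every read for downstream accuracy evaluation.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a uniform-random reference sequence
#'
#' @param length reference length in bases (>= 1).
#' @param seed integer seed fixing all randomness.
#' @param id record id.
#' @return a one-row reference `data.frame` (`id`, `seq`).
#' @export
simulate_reference <- function(length, seed = 1L, id = "ref1") {
  if (length < 1) stop("reference length must be >= 1")
  seq <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
                                      replace = TRUE), collapse = ""))
  data.frame(id = id, seq = seq, stringsAsFactors = FALSE)
}

#' @rdname simulate_reference
#' @param n number of references.
#' @param prefix id prefix (`ref01`, `ref02`, ...).
#' @export
simulate_references <- function(n, length, seed = 1L, prefix = "ref") {
  do.call(rbind, lapply(seq_len(n), function(i)
    simulate_reference(length, seed = seed + i - 1L,
                       id = sprintf("%s%02d", prefix, i))))
}

#' Simulation configuration
#'
#' Defines the artificial-read protocol: reads are length-`read_length`
#' windows at uniform random offsets of uniformly chosen references,
#' mutated per base with probability `error_rate`. Errored positions are
#' substitutions, insertions or deletions in the proportions given
#' (defaults 0.9/0.05/0.05).
#'
#' @param n_reads number of reads to draw.
#' @param read_length read length L in bases (default 100).
#' @param error_rate per-base error probability `e` in `[0, 1)`.
#' @param sub_frac,ins_frac,del_frac composition of errored positions;
#'   must sum to 1.
#' @param seed integer seed; identical configurations give byte-identical
#'   FASTQ output.
#' @param source_refs optional subset of reference ids (or indices) reads
#'   are drawn from, for mixture experiments.
#' @param strand `"forward"` (default) or `"both"` (reads drawn from either
#'   strand with probability 1/2).
#' @param n_source_sites optional redundancy mode: restrict sampling to
#'   this many pre-drawn (reference, offset) sites so that reads are
#'   heavily duplicated, emulating low-unique-fraction datasets.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_reads, read_length = 100L, error_rate = 0,
                       sub_frac = 0.9, ins_frac = 0.05, del_frac = 0.05,
                       seed = 1L, source_refs = NULL,
                       strand = c("forward", "both"),
                       n_source_sites = NULL) {
  strand <- match.arg(strand)
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (abs(sub_frac + ins_frac + del_frac - 1) > 1e-8)
    stop("sub_frac + ins_frac + del_frac must sum to 1")
  if (n_reads < 0) stop("n_reads must be >= 0")
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, sub_frac = sub_frac,
                 ins_frac = ins_frac, del_frac = del_frac,
                 seed = as.integer(seed), source_refs = source_refs,
                 strand = strand, n_source_sites = n_source_sites),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# apply planned errors to the window characters; errpos/types refer to
# source window positions 1..L
apply_errors <- function(wchars, L, errpos, types) {
  type_at <- character(length(wchars))
  type_at[errpos] <- types
  out <- character(L + length(errpos))
  oi <- 0L
  wi <- 1L
  ns <- ni <- nd <- 0L
  while (oi < L && wi <= length(wchars)) {
    ty <- type_at[wi]
    if (ty == "I") {
      oi <- oi + 1L
      out[oi] <- sample(BASES, 1L)
      ni <- ni + 1L
      type_at[wi] <- ""
      next
    }
    b <- wchars[wi]
    if (ty == "S") {
      oi <- oi + 1L
      out[oi] <- sample(setdiff(BASES, b), 1L)
      ns <- ns + 1L
    } else if (ty == "D") {
      nd <- nd + 1L
    } else {
      oi <- oi + 1L
      out[oi] <- b
    }
    wi <- wi + 1L
  }
  list(seq = paste(out[seq_len(oi)], collapse = ""),
       n_sub = ns, n_ins = ni, n_del = nd)
}

#' Simulate short reads with provenance
#'
#' Draws reads according to a [sim_config()] and records, for every read,
#' the source reference, 0-based source offset, strand, and the number of
#' injected substitutions/insertions/deletions (the truth table used by
#' [evaluate_against_truth()]).
#'
#' @param references a reference set (see [as_reference_set()]).
#' @param config a [sim_config()].
#' @return a list with elements `reads` (data.frame `id`, `seq`, `qual`)
#'   and `truth` (data.frame `read_id`, `ref_id`, `offset`, `strand`,
#'   `n_sub`, `n_ins`, `n_del`).
#' @export
simulate_reads <- function(references, config) {
  stopifnot(inherits(config, "sim_config"))
  refs <- as_reference_set(references)
  L <- config$read_length
  S <- config$n_reads
  G <- nchar(refs$seq)
  src_pool <- seq_len(nrow(refs))
  if (!is.null(config$source_refs)) {
    src_pool <- if (is.character(config$source_refs))
      match(config$source_refs, refs$id) else as.integer(config$source_refs)
    if (anyNA(src_pool) || any(src_pool < 1 | src_pool > nrow(refs)))
      stop("source_refs must name references present in the set")
  }
  if (any(G[src_pool] < L))
    stop("read_length exceeds the shortest source reference")

  with_seed(config$seed, {
    if (!is.null(config$n_source_sites)) {
      k <- as.integer(config$n_source_sites)
      site_src <- src_pool[sample.int(length(src_pool), k, replace = TRUE)]
      site_off <- floor(runif(k) * (G[site_src] - L + 1))
      pick <- sample.int(k, S, replace = TRUE)
      src <- site_src[pick]
      off <- site_off[pick]
    } else {
      src <- src_pool[sample.int(length(src_pool), S, replace = TRUE)]
      off <- floor(runif(S) * (G[src] - L + 1))
    }
    strands <- if (config$strand == "both")
      sample(c("+", "-"), S, replace = TRUE) else rep("+", S)

    seqs <- character(S)
    ns <- ni <- nd <- integer(S)
    e <- config$error_rate
    pfracs <- c(config$sub_frac, config$ins_frac, config$del_frac)
    for (i in seq_len(S)) {
      g <- G[src[i]]
      if (e == 0) {
        seqs[i] <- substr(refs$seq[src[i]], off[i] + 1L, off[i] + L)
      } else {
        errpos <- which(runif(L) < e)
        types <- if (length(errpos))
          sample(c("S", "I", "D"), length(errpos), replace = TRUE,
                 prob = pfracs) else character(0)
        wlen <- min(g - off[i], L + sum(types == "D"))
        w <- strsplit(substr(refs$seq[src[i]], off[i] + 1L,
                             off[i] + wlen), "")[[1]]
        m <- apply_errors(w, L, errpos, types)
        seqs[i] <- m$seq
        ns[i] <- m$n_sub; ni[i] <- m$n_ins; nd[i] <- m$n_del
      }
      if (strands[i] == "-") seqs[i] <- revcomp(seqs[i])
    }
    ids <- sprintf("read%06d", seq_len(S))
    list(reads = data.frame(id = ids, seq = seqs,
                            qual = strrep("I", nchar(seqs)),
                            stringsAsFactors = FALSE),
         truth = data.frame(read_id = ids, ref_id = refs$id[src],
                            offset = as.integer(off), strand = strands,
                            n_sub = ns, n_ins = ni, n_del = nd,
                            stringsAsFactors = FALSE))
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_reads, " reads x ", x$read_length, " bp, e = ",
      x$error_rate, " (S/I/D = ", x$sub_frac, "/", x$ins_frac, "/",
      x$del_frac, "), strand = ", x$strand, ", seed = ", x$seed, "\n",
      sep = "")
  invisible(x)
}
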