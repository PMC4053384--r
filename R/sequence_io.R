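#' Read a FASTA file of reference sequences
#'
#' Parses a (possibly multi-record, multi-line) FASTA file into a reference
#' table. Sequences are case-folded to upper case; record ids are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return a `data.frame` with columns `id` and `seq`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "AC", "GT", ">b", "TT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L)
    stop("FASTA format error at line 1: empty file")
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop("FASTA format error at line ", nonempty[1],
         ": expected a '>' header before sequence data")
  hdr <- which(startsWith(trimws(lines), ">"))
  for (h in hdr) {
    nxt <- lines[seq(h + 1L, length.out = max(0L, length(lines) - h))]
    nxt <- nxt[nzchar(trimws(nxt))]
    if (length(nxt) == 0L || startsWith(trimws(nxt[1]), ">"))
      stop("FASTA format error at line ", h, ": empty record")
  }
  x <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(x), "[ \t]"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate reference ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(id = ids, seq = toupper(as.character(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a FASTQ file of short reads
#'
#' Parses 4-line-per-record FASTQ (Sanger qualities). The per-base quality
#' string must have the same length as the sequence.
#'
#' @param path path to a FASTQ file.
#' @return a `data.frame` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L)
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  # structural validation first: the downstream parser assumes well-formed
  # 4-line records and misbehaves on malformed input
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ format error in ", path, ": truncated 4-line record")
  hd <- seq(1L, length(lines), by = 4L)
  if (!all(startsWith(lines[hd], "@")) ||
      !all(startsWith(lines[hd + 2L], "+")))
    stop("FASTQ format error in ", path, ": malformed record markers")
  bad <- which(nchar(lines[hd + 3L]) != nchar(lines[hd + 1L]))
  if (length(bad))
    stop("FASTQ format error in ", path, ": quality length differs from ",
         "sequence length for read '", sub("^@", "", lines[hd[bad[1]]]), "'")
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) stop("FASTQ format error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  ids <- vapply(strsplit(names(x), "[ \t]"), `[[`, "", 1L)
  seqs <- toupper(as.character(x))
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  data.frame(id = ids, seq = seqs, qual = qual,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences as FASTA / reads as FASTQ
#'
#' Deterministic plain-text writers (byte-identical output for identical
#' input), used by the simulator and the CLI.
#'
#' @param x for `write_fasta` a data.frame with `id`, `seq` (references);
#'   for `write_fastq` a data.frame with `id`, `seq`, `qual` (reads).
#' @param path output file path.
#' @param width line width for FASTA sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  x <- as_reference_set(x)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", x$id[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(x, path) {
  x <- as_read_set(x)
  qual <- x$qual
  qual[is.na(qual)] <- strrep("I", nchar(x$seq[is.na(qual)]))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", x$id), x$seq, "+", qual)), con)
  invisible(path)
}

#' Coerce to a reference set
#'
#' Accepts a data.frame with `id`/`seq`, a named character vector, a
#' `DNAStringSet`, or a FASTA file path. Validates non-empty sequences and
#' unique ids.
#'
#' @param x object to coerce.
#' @return a `data.frame` with columns `id`, `seq`.
#' @export
as_reference_set <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    x <- read_fasta(x)
  }
  if (methods::is(x, "DNAStringSet"))
    x <- data.frame(id = names(x), seq = as.character(x),
                    stringsAsFactors = FALSE)
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("ref", seq_along(x))
    x <- data.frame(id = ids, seq = unname(x), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  x$seq <- toupper(x$seq)
  if (any(!nzchar(x$seq))) stop("reference sequences must be non-empty")
  if (anyDuplicated(x$id)) stop("reference ids must be unique")
  x[c("id", "seq")]
}

#' @rdname as_reference_set
#' @export
as_read_set <- function(x) {
  if (methods::is(x, "DNAStringSet"))
    x <- data.frame(id = names(x), seq = as.character(x),
                    stringsAsFactors = FALSE)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- read_fastq(x)
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("read", seq_along(x))
    x <- data.frame(id = ids, seq = unname(x), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  if (is.null(x$qual)) x$qual <- NA_character_
  x$seq <- toupper(x$seq)
  if (any(!nzchar(x$seq))) stop("read sequences must be non-empty")
  bad <- which(!is.na(x$qual) & nchar(x$qual) != nchar(x$seq))
  if (length(bad))
    stop("read '", x$id[bad[1]], "': quality length differs from sequence")
  x[c("id", "seq", "qual")]
}

#' 2-bit nucleotide encoding
#'
#' Packs an ACGT string into 2-bit codes (A=0, C=1, G=2, T=3) with the
#' first base in the most significant bits, so the integer order of k-mer
#' codes equals the lexicographic order of k-mers.
#'
#' @param seq a single ACGT string (no ambiguity codes).
#' @return an object of class `twobit`.
#' @examples
#' decode_2na(encode_2na("ACGT"))
#' @export
encode_2na <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- cpp_encode_2na(toupper(seq))
  structure(x, class = "twobit")
}

#' @rdname encode_2na
#' @param x a `twobit` object.
#' @export
decode_2na <- function(x) {
  stopifnot(inherits(x, "twobit"))
  cpp_decode_2na(x$packed, x$length)
}

#' @export
print.twobit <- function(x, ...) {
  cat("<twobit> ", x$length, " bases, ", length(x$packed), " bytes\n", sep = "")
  invisible(x)
}

#' 2-na integer code of a k-mer
#'
#' @param seq a nucleotide string.
#' @param offset 0-based start of the k-mer window (vectorised).
#' @param k k-mer length (1..26; codes are exact doubles in that range).
#' @return numeric code(s) in `[0, 4^k)`; `NA` where the window contains an
#'   ambiguity base (the caller skips such seed positions).
#' @examples
#' kmer_code("ACGT", 0, 4) # 27
#' @export
kmer_code <- function(seq, offset = 0L, k) {
  stopifnot(is.character(seq), length(seq) == 1L)
  vapply(as.integer(offset), function(o) cpp_kmer_code(seq, o, as.integer(k)),
         numeric(1))
}

#' Reverse complement
#'
#' @param seqs character vector of nucleotide strings (N maps to N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seqs) cpp_revcomp(as.character(seqs))
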