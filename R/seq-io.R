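#' Build a sequence tibble
#'
#' The package-wide container for reads, references and contigs: one row per
#' sequence with an `id`, an upper-case `seq` over `{A,C,G,T,N}` and, when
#' present, a `qual` list column of integer Phred scores (one per base).
#'
#' @param id Character vector of identifiers.
#' @param seq Character vector of nucleotide sequences.
#' @param qual Optional list of integer Phred vectors, one per sequence.
#' @param circular Optional logical vector flagging circular sequences.
#' @param preserve_case Keep lower-case (soft-masked) bases instead of
#'   upper-casing; mask-aware consumers (gene-set placement) exclude them
#'   from seeding.
#' @return A tibble with columns `id`, `seq` and, if supplied, `qual` and
#'   `circular`.
#' @export
seq_tbl <- function(id, seq, qual = NULL, circular = NULL, preserve_case = FALSE) {
  seq <- normalize_bases(seq, preserve_case = preserve_case)
  out <- tibble(id = as.character(id), seq = seq)
  if (!is.null(qual)) {
    stopifnot(length(qual) == nrow(out))
    bad <- which(lengths(qual) != nchar(out$seq))
    if (length(bad) > 0) {
      abort(sprintf("quality length differs from sequence length for %d record(s), first id: %s",
                    length(bad), out$id[bad[1]]))
    }
    out$qual <- qual
  }
  if (!is.null(circular)) out$circular <- circular
  out
}

#' Read a FASTA file into a sequence tibble
#'
#' Record ids are the header token up to the first whitespace; multi-line
#' sequences are concatenated. Characters outside `{A,C,G,T,N}` are mapped to
#' `N` with a warning.
#'
#' @param path Path to a FASTA file.
#' @param preserve_case Keep lower-case (soft-masked) regions.
#' @return A [seq_tbl()] tibble (`id`, `seq`).
#' @export
read_fasta <- function(path, preserve_case = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e))))
  if (length(x) == 0) abort(sprintf("empty FASTA file (no records at line 1): %s", path))
  ids <- sub("\\s.*$", "", names(x))
  seq_tbl(id = ids, seq = unname(as.character(x)), preserve_case = preserve_case)
}

#' Write a sequence tibble as FASTA
#'
#' @param x A sequence tibble (`id`, `seq`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  check_seq_tbl(x, arg = "x")
  s <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(s, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a FASTQ file into a sequence tibble
#'
#' Qualities are decoded as `char code - phred_offset`. The default offset 33
#' is the modern Sanger/Illumina-1.8+ convention; pass `phred_offset = 64` for
#' early-Illumina (GAII pipeline) data, where the letter "B" encodes the
#' unscorable quality Q2.
#'
#' @param path Path to a FASTQ file.
#' @param phred_offset Either 33 or 64.
#' @return A [seq_tbl()] tibble (`id`, `seq`, `qual`).
#' @export
read_fastq <- function(path, phred_offset = 33L) {
  if (!phred_offset %in% c(33L, 64L)) abort("`phred_offset` must be 33 or 64")
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
                error = function(e) abort(sprintf("malformed FASTQ in %s: %s", path, conditionMessage(e))))
  if (length(x) == 0) abort(sprintf("empty FASTQ file: %s", path))
  ids <- sub("\\s.*$", "", names(x))
  qual_str <- unname(as.character(S4Vectors::mcols(x)$qualities))
  qual <- lapply(qual_str, function(s) utf8ToInt(s) - as.integer(phred_offset))
  if (any(unlist(qual, use.names = FALSE) < 0L)) {
    abort(sprintf("negative decoded quality: wrong `phred_offset` (%d) for %s", phred_offset, path))
  }
  seq_tbl(id = ids, seq = unname(as.character(x)), qual = qual)
}

#' Write a sequence tibble as FASTQ
#'
#' @param x A sequence tibble with a `qual` list column.
#' @param path Output path.
#' @param phred_offset Either 33 or 64.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path, phred_offset = 33L) {
  check_seq_tbl(x, need_qual = TRUE, arg = "x")
  if (!phred_offset %in% c(33L, 64L)) abort("`phred_offset` must be 33 or 64")
  qual_str <- vapply(x$qual, function(q) intToUtf8(q + as.integer(phred_offset)), character(1))
  s <- Biostrings::DNAStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(s, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual_str))
  invisible(path)
}

#' Ingest read placements from a SAM file
#'
#' Reads a header-bearing SAM file and returns one placement per primary
#' mapped record; unmapped, secondary and supplementary records are skipped
#' and counted in the `skipped` attribute. When `reference` is supplied the
#' per-placement match count and identity are recomputed by gapless
#' comparison of the aligned read against the reference.
#'
#' @param path Path to a SAM file (plain text).
#' @param reference Optional single-row sequence tibble used to recompute
#'   `matches` and `identity`.
#' @return A placement tibble (`read_id`, `ref_id`, `ref_start` (1-based),
#'   `strand`, `aligned_length`, `matches`, `identity`) with attribute
#'   `skipped` giving the number of non-primary/unmapped records.
#' @export
ingest_sam <- function(path, reference = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  hdr <- readLines(path, n = 200L)
  if (!any(startsWith(hdr, "@SQ"))) {
    abort(sprintf("SAM file %s has no @SQ reference line in its header", path))
  }
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE)
  prm <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "strand", "seq", "flag"),
                                 flag = flags)
  res <- Rsamtools::scanBam(bam, param = prm)[[1]]
  mapped <- !bitwAnd(res$flag, 4L)
  n_total <- length(Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = "flag"))[[1]]$flag)
  skipped <- n_total - sum(mapped)
  seqs <- as.character(res$seq)[mapped]
  out <- tibble(
    read_id = res$qname[mapped],
    ref_id = as.character(res$rname)[mapped],
    ref_start = res$pos[mapped],
    strand = as.character(res$strand)[mapped],
    aligned_length = nchar(seqs),
    matches = NA_integer_,
    identity = NA_real_
  )
  if (!is.null(reference) && nrow(out) > 0) {
    check_seq_tbl(reference, arg = "reference")
    ref <- reference$seq[match(out$ref_id, reference$id)]
    if (anyNA(ref)) abort("SAM records refer to a reference id absent from `reference`")
    # SAM SEQ is stored on the forward reference strand already
    refsub <- substr(ref, out$ref_start, out$ref_start + out$aligned_length - 1L)
    out$matches <- count_matches(seqs, refsub)
    out$identity <- out$matches / out$aligned_length
  }
  attr(out, "skipped") <- skipped
  out
}

# Vectorised match count between two equal-length character vectors of
# equal-width strings (grouped by width internally). N never matches.
count_matches <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(nchar(a) != nchar(b))) abort("alignment length mismatch (placement overruns reference end?)")
  out <- integer(length(a))
  wa <- nchar(a)
  for (w in unique(wa)) {
    i <- which(wa == w)
    if (w == 0) { out[i] <- 0L; next }
    ma <- str_to_raw_matrix(a[i], w)
    mb <- str_to_raw_matrix(b[i], w)
    eq <- (ma == mb) & (ma != charToRaw("N")[1])
    out[i] <- as.integer(colSums(eq))
  }
  out
}
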