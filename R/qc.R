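#' Remove N-containing and adapter-matching reads
#'
#' The first cleaning step of the skim pipeline: a read is removed if it
#' contains one or more `N` bases, or if any ungapped overlap of at least
#' `adapter_min_match` nt between the read and the adapter (either
#' orientation) reaches `adapter_min_identity`. Survivor order is preserved
#' and survivors are never modified.
#'
#' @param reads Sequence tibble.
#' @param adapter Adapter sequence; `NULL` disables adapter filtering.
#' @param adapter_min_match Minimum ungapped overlap length (nt).
#' @param adapter_min_identity Minimum identity over the overlap.
#' @return A list with `reads` (survivors) and `report` (one-row tibble:
#'   `n_input`, `n_removed_N`, `n_removed_adapter`, `n_kept`).
#' @export
remove_n_and_adapter <- function(reads, adapter = "AGATCGGAAGAGCGGTTCAG",
                                 adapter_min_match = 10L, adapter_min_identity = 0.9) {
  check_seq_tbl(reads)
  n_input <- nrow(reads)
  if (n_input == 0) {
    return(list(reads = reads,
                report = tibble(n_input = 0L, n_removed_N = 0L,
                                n_removed_adapter = 0L, n_kept = 0L)))
  }
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  is_adapter <- rep(FALSE, n_input)
  if (!is.null(adapter) && nzchar(adapter)) {
    todo <- which(!has_n)
    is_adapter[todo] <- matches_adapter(reads$seq[todo], toupper(adapter),
                                        adapter_min_match, adapter_min_identity)
  }
  keep <- !has_n & !is_adapter
  list(reads = reads[keep, , drop = FALSE],
       report = tibble(n_input = n_input,
                       n_removed_N = sum(has_n),
                       n_removed_adapter = sum(is_adapter),
                       n_kept = sum(keep)))
}

# TRUE for each read with a qualifying ungapped adapter overlap in either
# orientation. Vectorised over reads per (length, offset) pair.
matches_adapter <- function(seqs, adapter, min_match, min_identity) {
  out <- rep(FALSE, length(seqs))
  if (length(seqs) == 0) return(out)
  adapters <- unique(c(adapter, revcomp(adapter)))
  la <- nchar(adapter)
  widths <- nchar(seqs)
  for (w in unique(widths)) {
    idx <- which(widths == w & !out)
    if (length(idx) == 0) next
    m <- str_to_raw_matrix(seqs[idx], w)
    for (ad in adapters) {
      av <- charToRaw(ad)
      # offset d: adapter position 1 sits over read position d+1 (d may be
      # negative when the adapter starts before the read)
      for (d in seq(-(la - min_match), w - min_match)) {
        rs <- max(1L, d + 1L)
        re <- min(w, d + la)
        ov <- re - rs + 1L
        if (ov < min_match) next
        asub <- av[(rs - d):(re - d)]
        eq <- m[rs:re, , drop = FALSE] == matrix(asub, nrow = ov, ncol = ncol(m))
        hit <- colSums(eq) / ov >= min_identity
        if (any(hit)) out[idx[hit]] <- TRUE
      }
    }
  }
  out
}

#' Trim unscorable-quality tails
#'
#' The second cleaning step: each read is truncated at the first base whose
#' quality is at or below `unscorable_q` (default Q2, the early-Illumina "B"
#' value), removing that base and everything after it. Reads truncated to
#' length zero are dropped and counted as emptied.
#'
#' @param reads Sequence tibble with qualities.
#' @param unscorable_q Phred value at or below which a base starts the
#'   trimmed tail.
#' @return A list with `reads` (trimmed survivors) and `report` (one-row
#'   tibble: `n_input`, `n_emptied_by_trimming`, `n_kept`, `bases_in`,
#'   `bases_out`, `retained_fraction_after_trimming`).
#' @export
trim_quality_tails <- function(reads, unscorable_q = 2L) {
  check_seq_tbl(reads, need_qual = TRUE)
  n_input <- nrow(reads)
  if (n_input == 0) {
    return(list(reads = reads,
                report = tibble(n_input = 0L, n_emptied_by_trimming = 0L, n_kept = 0L,
                                bases_in = 0L, bases_out = 0L,
                                retained_fraction_after_trimming = NA_real_)))
  }
  cut_at <- vapply(reads$qual, function(q) {
    i <- which(q <= unscorable_q)
    if (length(i) == 0) length(q) else i[1] - 1L
  }, integer(1))
  bases_in <- sum(nchar(reads$seq))
  emptied <- cut_at == 0L
  out <- reads[!emptied, , drop = FALSE]
  keep_len <- cut_at[!emptied]
  out$seq <- substr(out$seq, 1L, keep_len)
  out$qual <- purrr::map2(out$qual, keep_len, ~ .x[seq_len(.y)])
  bases_out <- sum(keep_len)
  list(reads = out,
       report = tibble(n_input = n_input,
                       n_emptied_by_trimming = sum(emptied),
                       n_kept = sum(!emptied),
                       bases_in = bases_in, bases_out = bases_out,
                       retained_fraction_after_trimming = bases_out / bases_in))
}

#' Full read cleaning: N/adapter removal then tail trimming
#'
#' Runs the two cleaning steps in the pipeline's fixed order and returns both
#' pools: the cleaned (untrimmed) pool used for de novo work and the cleaned
#' and trimmed pool, together with a combined report.
#'
#' @inheritParams remove_n_and_adapter
#' @inheritParams trim_quality_tails
#' @return A list with `cleaned`, `trimmed` and a one-row `report` tibble.
#' @export
qc_reads <- function(reads, adapter = "AGATCGGAAGAGCGGTTCAG",
                     adapter_min_match = 10L, adapter_min_identity = 0.9,
                     unscorable_q = 2L) {
  step1 <- remove_n_and_adapter(reads, adapter, adapter_min_match, adapter_min_identity)
  step2 <- trim_quality_tails(step1$reads, unscorable_q)
  report <- tibble(
    n_input = step1$report$n_input,
    n_removed_N = step1$report$n_removed_N,
    n_removed_adapter = step1$report$n_removed_adapter,
    n_cleaned = step1$report$n_kept,
    n_emptied_by_trimming = step2$report$n_emptied_by_trimming,
    n_trimmed_kept = step2$report$n_kept,
    bases_in = step2$report$bases_in,
    bases_out = step2$report$bases_out,
    retained_fraction_after_trimming = step2$report$retained_fraction_after_trimming
  )
  list(cleaned = step1$reads, trimmed = step2$reads, report = report)
}
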