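# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

# Enumerate maximal perfect tandem repeats by regex backreference, one period
# at a time, keeping only primitive motifs (shortest-period attribution).
oracle_ssr_regex <- function(seq, min_units = c("2" = 4L, "3" = 4L, "4" = 3L,
                                                "5" = 3L, "6" = 3L)) {
  out <- list()
  for (p in as.integer(names(min_units))) {
    minu <- min_units[[as.character(p)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", p, minu - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      units <- lens[i] %/% p
      motif <- substr(seq, starts[i], starts[i] + p - 1L)
      # primitive motif check, independent implementation: a motif of length
      # p repeated is non-primitive iff the string equals one of its proper
      # rotations by a divisor shift
      primitive <- TRUE
      for (d in seq_len(p - 1)) {
        if (p %% d == 0 &&
            substr(strrep(substr(motif, 1, d), p), 1, p) == motif) {
          primitive <- FALSE
          break
        }
      }
      if (!primitive) next
      out[[length(out) + 1L]] <- data.frame(
        start = starts[i], end = starts[i] + units * p - 1L,
        motif = motif, motif_length = p, n_units = units,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0), motif = character(0),
                      motif_length = integer(0), n_units = integer(0)))
  }
  d <- do.call(rbind, out)
  d[order(d$start, d$motif_length), , drop = FALSE]
}

# Exhaustive gapless alignment of one read against a linear reference: every
# offset, both strands; returns the best placement at min_identity or NULL.
oracle_align_best <- function(read, refseq, min_identity) {
  L <- nchar(read)
  n <- nchar(refseq)
  if (L > n) return(NULL)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else rc
    qv <- strsplit(q, "")[[1]]
    for (o in seq_len(n - L + 1L)) {
      rv <- strsplit(substr(refseq, o, o + L - 1L), "")[[1]]
      m <- sum(qv == rv & qv != "N")
      if (m / L < min_identity) next
      if (is.null(best) || m > best$matches ||
          (m == best$matches && (o < best$start ||
                                 (o == best$start && strand == "+" && best$strand == "-")))) {
        best <- list(start = o, strand = strand, matches = m)
      }
    }
  }
  best
}

# N50 by direct definition over all candidate lengths.
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  min(lengths)
}

# Maximal exact matching runs per diagonal, both kinds; oracle for planted
# exact repeats (identity 1) longer than min_len.
oracle_exact_repeats <- function(seq, min_len, kind = c("direct", "inverted")) {
  kind <- match.arg(kind)
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  y <- if (kind == "direct") x else
    strsplit(as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq))), "")[[1]]
  out <- list()
  for (d in seq(-(n - 1L), n - 1L)) {
    i0 <- max(1L, 1L - d)
    i1 <- min(n, n - d)
    if (i1 - i0 + 1L <= min_len) next
    eq <- x[i0:i1] == y[(i0:i1) + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths > min_len)) {
      i <- i0 + starts[j] - 1L
      l <- r$lengths[j]
      jj <- i + d
      if (kind == "direct") {
        if (d == 0) next
        sa <- c(i, i + l - 1L); sb <- c(jj, jj + l - 1L)
      } else {
        sa <- c(i, i + l - 1L)
        sb <- c(n - (jj + l - 1L) + 1L, n - jj + 1L)
      }
      sp <- rbind(sa, sb)
      sp <- sp[order(sp[, 1]), , drop = FALSE]
      if (all(sp[1, ] == sp[2, ])) next
      out[[length(out) + 1L]] <- data.frame(
        start_a = sp[1, 1], end_a = sp[1, 2], start_b = sp[2, 1], end_b = sp[2, 2],
        length = l)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start_a = integer(0), end_a = integer(0),
                      start_b = integer(0), end_b = integer(0), length = integer(0)))
  }
  d <- unique(do.call(rbind, out))
  d[order(d$start_a, d$start_b), , drop = FALSE]
}

# Minimal SAM writer for ingestion tests (plain text, ungapped alignments).
write_test_sam <- function(placements, reads, reference, path) {
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", reference$id[[1]], nchar(reference$seq[[1]])))
  for (i in seq_len(nrow(placements))) {
    p <- placements[i, ]
    rseq <- reads$seq[match(p$read_id, reads$id)]
    flag <- if (p$strand == "-") 16L else 0L
    if (p$strand == "-") {
      rseq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rseq)))
    }
    lines <- c(lines, paste(p$read_id, flag, p$ref_id, p$ref_start, 60L,
                            paste0(nchar(rseq), "M"), "*", 0L, 0L, rseq, "*",
                            sep = "\t"))
  }
  writeLines(lines, path)
  path
}

# Small genome spec used by several tests: realistic compartment fractions,
# modest rDNA arrays, no planted nuclear features.
small_skim_spec <- function(seed = 1L, ...) {
  genome_spec(
    plastome = list(lsc_len = 1200L, ir_len = 250L, ssc_len = 300L),
    mito_contig_lengths = c(800L, 600L),
    rdna_cistron = list(unit_len = 600L, n_copies = 8L, poly_site_rate = 0.01,
                        minor_copy_fraction_range = c(0.1, 0.3)),
    rdna_5s = list(unit_len = 120L, n_copies = 20L, poly_site_rate = 0.1,
                   minor_copy_fraction_range = c(0.1, 0.3)),
    ssr_plan = NULL, repeat_families = NULL,
    control_sequence_length = 600L,
    seed = seed, ...)
}
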