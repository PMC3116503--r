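#' Classify reads into genome compartments
#'
#' Each read is assigned to the first compartment, in a fixed priority order
#' (chloroplast, mitochondrial, rdna, control, then any extra labels in the
#' order given), for which it has a qualifying placement on any reference of
#' that compartment; reads matching nothing are labelled `nuclear`
#' (unclassified). The priority order makes classification deterministic and
#' read-order independent when references share sequence (e.g. organellar
#' insertions).
#'
#' @param reads Sequence tibble.
#' @param compartment_refs Sequence tibble of references with a
#'   `compartment` label column (e.g. the genome tibble from
#'   [build_mock_genome()] minus the nuclear rows), or a named list of
#'   sequence tibbles.
#' @param seed_len Seed length for placement.
#' @param min_identity Minimum identity for a qualifying placement.
#' @param seed_stride Seed spacing passed to [place_reads()].
#' @return A list with `assignments` (tibble `read_id`, `compartment`) and
#'   `summary` (tibble `compartment`, `n_reads`, `fraction`, `bases`).
#' @export
classify_reads <- function(reads, compartment_refs, seed_len = 11L,
                           min_identity = 0.90, seed_stride = 1L) {
  check_seq_tbl(reads)
  if (is.list(compartment_refs) && !is.data.frame(compartment_refs)) {
    compartment_refs <- bind_rows(lapply(names(compartment_refs), function(nm) {
      x <- compartment_refs[[nm]]
      x$compartment <- nm
      x
    }))
  }
  check_seq_tbl(compartment_refs, arg = "compartment_refs")
  if (!"compartment" %in% names(compartment_refs)) {
    abort("`compartment_refs` needs a `compartment` column")
  }
  priority <- c("chloroplast", "mitochondrial", "rdna", "control")
  labels <- unique(compartment_refs$compartment)
  labels <- c(intersect(priority, labels), setdiff(labels, priority))

  assigned <- rep(NA_character_, nrow(reads))
  for (lab in labels) {
    todo <- which(is.na(assigned))
    if (length(todo) == 0) break
    refs <- compartment_refs[compartment_refs$compartment == lab, , drop = FALSE]
    hit <- rep(FALSE, length(todo))
    for (i in seq_len(nrow(refs))) {
      pl <- place_reads(reads[todo, , drop = FALSE], refs[i, , drop = FALSE],
                        seed_len = seed_len, min_identity = min_identity,
                        max_hits_per_read = 1L, seed_stride = seed_stride)
      hit <- hit | reads$id[todo] %in% pl$read_id
    }
    assigned[todo[hit]] <- lab
  }
  assigned[is.na(assigned)] <- "nuclear"
  total <- nrow(reads)
  summary <- tibble(read_id = reads$id, compartment = assigned,
                    bases = nchar(reads$seq)) %>%
    group_by(.data$compartment) %>%
    summarise(n_reads = n(), bases = sum(.data$bases), .groups = "drop") %>%
    mutate(fraction = .data$n_reads / total) %>%
    arrange(match(.data$compartment, c(labels, "nuclear")))
  list(assignments = tibble(read_id = reads$id, compartment = assigned),
       summary = summary[, c("compartment", "n_reads", "fraction", "bases")])
}

#' Overall and nuclear genome coverage from sequencing yield
#'
#' Overall coverage is `total_bases / genome_size`; nuclear coverage removes
#' the read fractions attributable to the high-copy compartments
#' (organelles, rDNA): `total_bases * (1 - sum(fractions)) / genome_size`.
#' Both are also reported rounded to one decimal, the precision at which
#' such "approximately" figures are quoted.
#'
#' @param total_bases Sequencing yield in bases.
#' @param genome_size Haploid genome size in bases.
#' @param fractions Numeric vector of high-copy compartment read fractions
#'   (may be empty).
#' @return One-row tibble: `total_bases`, `genome_size`, `overall_coverage`,
#'   `nuclear_coverage`, `overall_rounded`, `nuclear_rounded`.
#' @export
estimate_genome_coverage <- function(total_bases, genome_size, fractions = numeric(0)) {
  if (genome_size <= 0) abort("`genome_size` must be positive")
  stopifnot(all(fractions >= 0), all(fractions <= 1), sum(fractions) < 1)
  overall <- total_bases / genome_size
  nuclear <- total_bases * (1 - sum(fractions)) / genome_size
  tibble(total_bases = total_bases, genome_size = genome_size,
         overall_coverage = overall, nuclear_coverage = nuclear,
         overall_rounded = round(overall, 1), nuclear_rounded = round(nuclear, 1))
}

#' Repeat copy number from median depth and single-copy coverage
#'
#' Using the median read depth of a repeat's assembly as an estimate of the
#' number of copies sequenced, the copy number per genome is the ratio of
#' that depth to the single-copy (nuclear) coverage.
#'
#' @param median_depth Median read depth over the repeat consensus (fold).
#' @param nuclear_coverage Single-copy nuclear coverage (fold).
#' @return One-row tibble: `copies` (unrounded), `copies_rounded` (integer).
#' @export
estimate_copy_number <- function(median_depth, nuclear_coverage) {
  if (any(nuclear_coverage <= 0)) abort("`nuclear_coverage` must be positive")
  copies <- median_depth / nuclear_coverage
  tibble(median_depth = median_depth, nuclear_coverage = nuclear_coverage,
         copies = copies, copies_rounded = as.integer(round(copies)))
}

#' Convert a flow-cytometry 2C value to a haploid genome size
#'
#' Applies the standard conversion 1 pg = 978 Mbp to half the 2C DNA mass:
#' `1C Mbp = (2C pg / 2) * 978`. The rounded value (nearest 5 Mbp) matches
#' the precision at which such genome sizes are quoted.
#'
#' @param two_c_picograms 2C DNA content in picograms.
#' @return A tibble: `two_c_pg`, `mbp_1c` (raw), `mbp_1c_rounded`
#'   (nearest 5 Mbp).
#' @export
pg_to_mbp <- function(two_c_picograms) {
  if (any(two_c_picograms <= 0)) abort("2C value must be positive")
  mbp <- (two_c_picograms / 2) * 978
  tibble(two_c_pg = two_c_picograms, mbp_1c = mbp,
         mbp_1c_rounded = round(mbp / 5) * 5)
}
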