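#' Place reads on a reference by gapless seed-and-extend
#'
#' Candidate diagonals come from exact seed (k-mer) hits on both strands;
#' each candidate is extended without gaps over the full read and reported
#' when its identity reaches `min_identity`. Hits are ordered best-identity
#' first with ties broken by lower reference position then `+` strand, and at
#' most `max_hits_per_read` are kept per read. Circular references are
#' handled by a virtual extension of the first `read length - 1` bases, with
#' start positions always reported on the original coordinates.
#'
#' N bases (in read or reference) never seed and always count as mismatches.
#'
#' @param reads Sequence tibble.
#' @param reference Single-row sequence tibble (optionally with a `circular`
#'   flag column).
#' @param seed_len Exact-seed length (k); must be at least 4.
#' @param min_identity Minimum identity over the full read.
#' @param max_hits_per_read Maximum placements reported per read.
#' @param seed_stride Spacing of seed offsets along the read; 1 (default)
#'   indexes every offset.
#' @param honor_softmask If `TRUE`, lower-case (masked) reference regions are
#'   excluded from seeding (extension still uses the real bases).
#' @return Placement tibble: `read_id`, `ref_id`, `ref_start` (1-based),
#'   `strand`, `aligned_length`, `matches`, `identity`.
#' @export
place_reads <- function(reads, reference, seed_len = 11L, min_identity = 0.85,
                        max_hits_per_read = 1L, seed_stride = 1L,
                        honor_softmask = FALSE) {
  check_seq_tbl(reads)
  if (!is.data.frame(reference) || nrow(reference) != 1) {
    abort("`reference` must be a single-row sequence tibble")
  }
  if (seed_len < 4) abort("`seed_len` < 4 gives a degenerate index")
  ref_raw <- reference$seq[[1]]
  index_src <- if (honor_softmask) chartr("acgtn", "NNNNN", ref_raw) else toupper(ref_raw)
  ref <- toupper(ref_raw)
  circular <- "circular" %in% names(reference) && isTRUE(reference$circular[[1]])
  if (nrow(reads) == 0) return(empty_placements())
  maxlen <- max(nchar(reads$seq))
  if (circular && maxlen > 1) {
    ref <- paste0(ref, substr(ref, 1L, maxlen - 1L))
    index_src <- paste0(index_src, substr(index_src, 1L, maxlen - 1L))
  }
  res <- cpp_place_reads(reads$seq, ref, index_src, as.integer(seed_len),
                         min_identity, as.integer(max_hits_per_read),
                         as.integer(seed_stride))
  tibble(
    read_id = reads$id[res$read],
    ref_id = reference$id[[1]],
    ref_start = res$start,
    strand = ifelse(res$strand == 0L, "+", "-"),
    aligned_length = res$aligned_length,
    matches = res$matches,
    identity = res$matches / res$aligned_length
  )
}

empty_placements <- function() {
  tibble(read_id = character(0), ref_id = character(0), ref_start = integer(0),
         strand = character(0), aligned_length = integer(0), matches = integer(0),
         identity = numeric(0))
}

#' Build a per-position pileup from placements
#'
#' Each aligned read base (reverse complemented for `-` strand placements)
#' increments exactly one column. `N` read bases increment the column's `n`
#' count and the total depth, but are excluded from majority calls and
#' discordance denominators downstream.
#'
#' @param placements Placement tibble from [place_reads()] or [ingest_sam()].
#' @param reads Sequence tibble the placements refer to.
#' @param reference Single-row sequence tibble.
#' @return Pileup tibble covering every reference position: `ref_id`, `pos`
#'   (1-based), `a`, `c`, `g`, `t`, `n`, `depth`.
#' @export
build_pileup <- function(placements, reads, reference) {
  check_seq_tbl(reads)
  stopifnot(nrow(reference) == 1)
  ref_len <- nchar(reference$seq[[1]])
  circular <- "circular" %in% names(reference) && isTRUE(reference$circular[[1]])
  counts <- matrix(0L, nrow = ref_len, ncol = 5,
                   dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  if (nrow(placements) > 0) {
    idx <- match(placements$read_id, reads$id)
    if (anyNA(idx)) abort("placements refer to read ids absent from `reads`")
    seqs <- reads$seq[idx]
    if (any(nchar(seqs) != placements$aligned_length)) {
      abort("placement aligned_length differs from read length")
    }
    neg <- placements$strand == "-"
    seqs[neg] <- revcomp(seqs[neg])
    lens <- placements$aligned_length
    if (!circular && any(placements$ref_start + lens - 1L > ref_len)) {
      abort("placement overruns the end of a linear reference")
    }
    pos <- unlist(purrr::map2(placements$ref_start, lens, ~ .x + seq_len(.y) - 1L),
                  use.names = FALSE)
    if (circular) pos <- ((pos - 1L) %% ref_len) + 1L
    base <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
    code <- match(base, c("A", "C", "G", "T"))
    code[is.na(code)] <- 5L
    tab <- tabulate((pos - 1L) * 5L + code, nbins = ref_len * 5L)
    counts <- matrix(tab, nrow = ref_len, ncol = 5, byrow = TRUE,
                     dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  }
  tibble(
    ref_id = reference$id[[1]],
    pos = seq_len(ref_len),
    a = counts[, "A"], c = counts[, "C"], g = counts[, "G"], t = counts[, "T"],
    n = counts[, "N"],
    depth = as.integer(rowSums(counts))
  )
}

#' Consensus masking policy
#'
#' @param min_depth Minimum effective (non-N) depth for an unmasked call.
#' @param min_major_proportion Minimum majority-base proportion (over non-N
#'   counts) for an unmasked call.
#' @param snp_min_minor_proportion Second-base proportion at or above which a
#'   position is treated as a SNP and masked.
#' @param snp_mask_mode One of `"N"` (mask to N), `"IUPAC"` (two-base
#'   ambiguity code) or `"off"`.
#' @return A `mask_policy` list.
#' @export
mask_policy <- function(min_depth = 3L, min_major_proportion = 0.7,
                        snp_min_minor_proportion = 0.2,
                        snp_mask_mode = c("N", "IUPAC", "off")) {
  snp_mask_mode <- match.arg(snp_mask_mode)
  stopifnot(min_depth >= 1, min_major_proportion > 0, min_major_proportion <= 1,
            snp_min_minor_proportion > 0, snp_min_minor_proportion <= 1)
  structure(list(min_depth = as.integer(min_depth),
                 min_major_proportion = min_major_proportion,
                 snp_min_minor_proportion = snp_min_minor_proportion,
                 snp_mask_mode = snp_mask_mode),
            class = "mask_policy")
}

iupac2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Call a masked consensus from a pileup
#'
#' The consensus base at each covered position is the majority base over the
#' non-N counts (ties broken alphabetically and flagged). A position is
#' masked to `N` when its effective depth is below `min_depth` or its
#' majority proportion is below `min_major_proportion`; if SNP masking is on
#' and the second-most-common base reaches `snp_min_minor_proportion`, the
#' position is masked to `N` or to the two-base IUPAC code. Contigs are
#' maximal runs of positions with non-zero depth.
#'
#' @param pileup Pileup tibble from [build_pileup()].
#' @param policy A [mask_policy()].
#' @return A list with `contigs` (tibble: `ref_id`, `start`, `end` (1-based
#'   inclusive), `length`, `sequence`, `median_depth`) and `columns` (the
#'   pileup with `consensus_base`, `masked` and `tie` columns).
#' @export
call_consensus <- function(pileup, policy = mask_policy()) {
  stopifnot(inherits(policy, "mask_policy"))
  m <- as.matrix(pileup[, c("a", "c", "g", "t")])
  colnames(m) <- c("A", "C", "G", "T")
  eff <- as.integer(rowSums(m))
  ord_first <- max.col(m, ties.method = "first")
  ord_last <- max.col(m, ties.method = "last")
  tie <- ord_first != ord_last & eff > 0
  maj_count <- m[cbind(seq_len(nrow(m)), ord_first)]
  maj_base <- colnames(m)[ord_first]
  m2 <- m
  m2[cbind(seq_len(nrow(m)), ord_first)] <- -1L
  sec_idx <- max.col(m2, ties.method = "first")
  sec_count <- m[cbind(seq_len(nrow(m)), sec_idx)]
  sec_base <- colnames(m)[sec_idx]
  maj_prop <- ifelse(eff > 0, maj_count / eff, 0)
  sec_prop <- ifelse(eff > 0, sec_count / eff, 0)

  base <- maj_base
  masked <- eff < policy$min_depth | maj_prop < policy$min_major_proportion
  base[masked] <- "N"
  if (policy$snp_mask_mode != "off") {
    is_snp <- !masked & sec_prop >= policy$snp_min_minor_proportion & sec_count > 0
    if (policy$snp_mask_mode == "N") {
      base[is_snp] <- "N"
    } else {
      key <- paste0(pmin(maj_base[is_snp], sec_base[is_snp]),
                    pmax(maj_base[is_snp], sec_base[is_snp]))
      base[is_snp] <- unname(iupac2[key])
    }
    masked <- masked | is_snp
  }
  covered <- pileup$depth > 0
  base[!covered] <- NA_character_

  columns <- pileup
  columns$consensus_base <- base
  columns$masked <- masked & covered
  columns$tie <- tie

  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  contigs <- tibble(
    ref_id = rep(pileup$ref_id[[1]], length(runs)),
    start = starts[runs],
    end = ends[runs]
  )
  if (nrow(contigs) > 0) {
    contigs$length <- contigs$end - contigs$start + 1L
    contigs$sequence <- vapply(seq_len(nrow(contigs)), function(i) {
      paste(base[contigs$start[i]:contigs$end[i]], collapse = "")
    }, character(1))
    contigs$median_depth <- vapply(seq_len(nrow(contigs)), function(i) {
      median(pileup$depth[contigs$start[i]:contigs$end[i]])
    }, numeric(1))
  } else {
    contigs$length <- integer(0)
    contigs$sequence <- character(0)
    contigs$median_depth <- numeric(0)
  }
  list(contigs = contigs, columns = columns)
}

#' Assembly statistics for a consensus
#'
#' N50 is the length L such that contigs of length at least L sum to at least
#' half of the total contig length (descending cumulative sum); the median
#' depth is taken over all covered positions of the pileup.
#'
#' @param contigs Contig tibble from [call_consensus()].
#' @param pileup Pileup tibble the contigs were called from.
#' @return One-row tibble: `n_contigs`, `n50`, `longest`, `total_bases`,
#'   `median_depth`.
#' @export
assembly_stats <- function(contigs, pileup) {
  if (nrow(contigs) == 0) abort("no contigs: cannot compute assembly statistics")
  lens <- sort(contigs$length, decreasing = TRUE)
  n50 <- lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
  covered <- pileup$depth[pileup$depth > 0]
  tibble(n_contigs = nrow(contigs), n50 = n50, longest = lens[1],
         total_bases = sum(lens), median_depth = median(covered))
}
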