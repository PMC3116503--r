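#' Quality filter reads for polymorphism quantification
#'
#' Reads with mean Phred score strictly below `min_avg_q` are discarded; in
#' the survivors every base with a score strictly below `min_base_q` is
#' replaced by `N` (length preserved), so that unreliable bases drop out of
#' both numerator and denominator of the discordance proportions.
#'
#' @param reads Sequence tibble with qualities.
#' @param min_avg_q Minimum mean Phred score to keep a read.
#' @param min_base_q Per-base Phred score below which a base becomes `N`.
#' @return A list with `reads` (filtered/masked) and `report` (one-row
#'   tibble: `n_input`, `n_removed_low_mean`, `n_kept`, `bases_masked`,
#'   `fraction_bases_masked`).
#' @export
quality_filter_for_polymorphism <- function(reads, min_avg_q = 20, min_base_q = 20) {
  check_seq_tbl(reads, need_qual = TRUE)
  n_input <- nrow(reads)
  if (n_input == 0) {
    return(list(reads = reads,
                report = tibble(n_input = 0L, n_removed_low_mean = 0L, n_kept = 0L,
                                bases_masked = 0L, fraction_bases_masked = NA_real_)))
  }
  mean_q <- vapply(reads$qual, mean, numeric(1))
  keep <- mean_q >= min_avg_q
  out <- reads[keep, , drop = FALSE]
  bases_masked <- 0L
  if (nrow(out) > 0) {
    low <- lapply(out$qual, function(q) which(q < min_base_q))
    nlow <- lengths(low)
    bases_masked <- sum(nlow)
    todo <- which(nlow > 0)
    for (i in todo) {
      s <- strsplit(out$seq[i], "", fixed = TRUE)[[1]]
      s[low[[i]]] <- "N"
      out$seq[i] <- paste(s, collapse = "")
    }
  }
  list(reads = out,
       report = tibble(n_input = n_input,
                       n_removed_low_mean = sum(!keep),
                       n_kept = sum(keep),
                       bases_masked = bases_masked,
                       fraction_bases_masked = bases_masked / sum(nchar(out$seq))))
}

#' Per-position discordance against a consensus
#'
#' At each position the number of (non-N) read bases differing from the
#' consensus base is tallied and expressed as a proportion of the effective
#' depth. Positions with zero effective depth, or where the consensus itself
#' is masked, carry `NA` proportions (missing, not zero).
#'
#' @param pileup Pileup tibble from [build_pileup()].
#' @param consensus Consensus sequence as a single string (same length as
#'   the pileup), e.g. a template or the self-consensus from
#'   [call_consensus()].
#' @return A `discordance_profile` tibble: `ref_id`, `pos`,
#'   `depth_effective`, `n_discordant`, `proportion`, `consensus_base`.
#' @export
discordance_profile <- function(pileup, consensus) {
  stopifnot(is.character(consensus), length(consensus) == 1)
  if (nchar(consensus) != nrow(pileup)) {
    abort(sprintf("consensus length (%d) differs from pileup span (%d)",
                  nchar(consensus), nrow(pileup)))
  }
  cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  m <- as.matrix(pileup[, c("a", "c", "g", "t")])
  colnames(m) <- c("A", "C", "G", "T")
  eff <- as.integer(rowSums(m))
  ci <- match(cons, colnames(m))
  agree <- ifelse(is.na(ci), NA_integer_, m[cbind(seq_along(ci), ifelse(is.na(ci), 1L, ci))])
  n_disc <- eff - agree
  prop <- ifelse(eff > 0 & !is.na(ci), n_disc / eff, NA_real_)
  out <- tibble(ref_id = pileup$ref_id, pos = pileup$pos,
                depth_effective = eff,
                n_discordant = ifelse(is.na(prop), NA_integer_, n_disc),
                proportion = prop,
                consensus_base = cons)
  class(out) <- c("discordance_profile", class(out))
  out
}

#' Call polymorphic positions from a discordance profile
#'
#' Positions whose discordance proportion reaches `threshold` (default 2%)
#' are called polymorphic. The percentage of polymorphic sites is reported
#' per annotated region (and for the whole profile span) as
#' `100 * calls / region length`, to one decimal.
#'
#' @param profile A [discordance_profile()] tibble.
#' @param threshold Minimum proportion of differing reads for a call.
#' @param regions Optional BED-style tibble (`region`, `start`, `end`,
#'   1-based inclusive) for per-region percentages.
#' @return A list with `positions` (integer vector of called positions),
#'   `threshold`, and `summary` (tibble: `region`, `length`, `n_polymorphic`,
#'   `percent_polymorphic`).
#' @export
call_polymorphic <- function(profile, threshold = 0.02, regions = NULL) {
  calls <- profile$pos[!is.na(profile$proportion) & profile$proportion >= threshold]
  span <- nrow(profile)
  summ <- tibble(region = "all", length = span, n_polymorphic = length(calls),
                 percent_polymorphic = round(100 * length(calls) / span, 1))
  if (!is.null(regions)) {
    per <- purrr::pmap_dfr(regions, function(region, start, end, ...) {
      len <- end - start + 1L
      n <- sum(calls >= start & calls <= end)
      tibble(region = region, length = len, n_polymorphic = n,
             percent_polymorphic = round(100 * n / len, 1))
    })
    summ <- bind_rows(summ, per)
  }
  list(positions = calls, threshold = threshold, summary = summ)
}

#' Summarise a control-sequence error profile
#'
#' Applied to the discordance profile of a spiked control (e.g. a
#' PhiX-style lane control), this reports the overall mean discordance, the
#' maximum-discordance position, and how many positions exceed each given
#' cutoff — the empirical error calibration that justifies the polymorphism
#' threshold.
#'
#' @param profile A [discordance_profile()] computed on the control.
#' @param cutoffs Proportion cutoffs to count exceedances for.
#' @return A list with `overall_mean_discordance`, `max_position` (one-row
#'   tibble `pos`, `proportion`), and `n_positions_above` (tibble `cutoff`,
#'   `n_above`).
#' @export
control_error_profile <- function(profile, cutoffs = 0.007) {
  ok <- !is.na(profile$proportion)
  if (!any(ok)) abort("control profile has no informative positions")
  props <- profile$proportion[ok]
  imax <- which.max(props)
  list(
    overall_mean_discordance = mean(props),
    max_position = tibble(pos = profile$pos[ok][imax], proportion = props[imax]),
    n_positions_above = tibble(cutoff = cutoffs,
                               n_above = vapply(cutoffs, function(x) sum(props > x), integer(1)))
  )
}
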