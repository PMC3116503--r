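#' Specify a mock multi-compartment genome
#'
#' Describes the genome a skim is drawn from: a single-copy nuclear
#' background, a circular quadripartite plastome present in many copies per
#' cell, a set of mitochondrial contigs, two tandem rDNA arrays (the large
#' 18S-5.8S-26S cistron and the short 5S unit) whose copies carry controlled
#' intragenomic polymorphism, an error-calibration control sequence, and
#' planted SSR loci and dispersed repeat families.
#'
#' The default parameters mirror the conditions a low-coverage plant genome
#' skim saturates: chloroplast/mitochondrial/rDNA read fractions of 11.8%,
#' 3.4% and 1.8%; a 7,541 bp cistron unit with a polymorphic-site rate of
#' 19/7541 (about 0.3% of sites); a 120 bp 5S unit with 26.7% of sites
#' polymorphic; minor-copy fractions between 2% and 17%. Copy numbers of the
#' organellar and rDNA compartments are expressed as sampling weights; the
#' nuclear background length is solved so the target read fractions hold
#' exactly in expectation.
#'
#' @param target_fractions Named numeric: expected read fractions for
#'   `chloroplast`, `mitochondrial` and `rdna` (remainder nuclear + control).
#' @param plastome List with `lsc_len`, `ir_len`, `ssc_len` (bp).
#' @param mito_contig_lengths Integer vector of mitochondrial contig lengths.
#' @param rdna_cistron,rdna_5s Lists with `unit_len`, `n_copies`,
#'   `poly_site_rate` (fraction of sites) or `n_poly_sites` (exact count),
#'   and `minor_copy_fraction_range` (length-2 in (0, 0.5]).
#' @param ssr_plan Tibble/data frame with columns `motif`, `n_units`, `count`
#'   of SSR loci to plant in the nuclear background.
#' @param repeat_families Tibble/data frame with columns `family`,
#'   `element_length`, `copy_count` of dispersed repeats to plant.
#' @param control_sequence_length Length of the spiked control sequence (bp);
#'   0 disables it.
#' @param nuclear_length Nuclear background length; `NULL` (default) solves it
#'   from `target_fractions` and the organellar/rDNA weights.
#' @param seed Integer seed; the whole genome build is a deterministic
#'   function of the spec.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(target_fractions = c(chloroplast = 0.118, mitochondrial = 0.034, rdna = 0.018),
                        plastome = list(lsc_len = 3000L, ir_len = 600L, ssc_len = 500L),
                        mito_contig_lengths = c(2000L, 1500L),
                        rdna_cistron = list(unit_len = 7541L, n_copies = 10L,
                                            poly_site_rate = 19 / 7541,
                                            minor_copy_fraction_range = c(0.02, 0.17)),
                        rdna_5s = list(unit_len = 120L, n_copies = 40L,
                                       poly_site_rate = 0.267,
                                       minor_copy_fraction_range = c(0.02, 0.17)),
                        ssr_plan = default_ssr_plan(),
                        repeat_families = default_repeat_families(),
                        control_sequence_length = 5386L,
                        nuclear_length = NULL,
                        seed = 1L) {
  f <- target_fractions
  stopifnot(all(c("chloroplast", "mitochondrial", "rdna") %in% names(f)),
            all(f > 0), sum(f) < 1)
  stopifnot(plastome$lsc_len > 0, plastome$ir_len > 0, plastome$ssc_len > 0)
  for (rd in list(rdna_cistron, rdna_5s)) {
    stopifnot(rd$unit_len > 0, rd$n_copies >= 1)
    rng <- rd$minor_copy_fraction_range
    stopifnot(length(rng) == 2, rng[1] > 0, rng[2] <= 0.5, rng[1] <= rng[2])
  }
  plast_len <- plastome$lsc_len + 2L * plastome$ir_len + plastome$ssc_len
  w_rdna <- rdna_cistron$unit_len * rdna_cistron$n_copies +
    rdna_5s$unit_len * rdna_5s$n_copies
  w_total <- w_rdna / f[["rdna"]]
  w_chl <- f[["chloroplast"]] * w_total
  w_mit <- f[["mitochondrial"]] * w_total
  w_nuc <- w_total - w_rdna - w_chl - w_mit - control_sequence_length
  if (is.null(nuclear_length)) {
    nuclear_length <- as.integer(round(w_nuc))
    if (nuclear_length < 1000L) {
      abort("solved nuclear length < 1 kb; lower the rDNA weight or the control length")
    }
  }
  structure(list(
    target_fractions = f,
    plastome = plastome,
    plastome_copy = w_chl / plast_len,
    mito_contig_lengths = as.integer(mito_contig_lengths),
    mito_copy = w_mit / sum(mito_contig_lengths),
    rdna_cistron = rdna_cistron,
    rdna_5s = rdna_5s,
    ssr_plan = if (is.null(ssr_plan)) tibble() else as_tibble(ssr_plan),
    repeat_families = if (is.null(repeat_families)) tibble() else as_tibble(repeat_families),
    control_sequence_length = as.integer(control_sequence_length),
    nuclear_length = as.integer(nuclear_length),
    seed = as.integer(seed)
  ), class = "genome_spec")
}

#' @rdname genome_spec
#' @export
default_ssr_plan <- function() {
  tibble(motif = c("TA", "GA", "ATTC", "CCT"),
         n_units = c(6L, 5L, 4L, 4L),
         count = c(2L, 2L, 1L, 1L))
}

#' @rdname genome_spec
#' @export
default_repeat_families <- function() {
  tibble(family = c("copia_like", "gypsy_like"),
         element_length = c(300L, 250L),
         copy_count = c(6L, 4L))
}

# Instantiate a tandem rDNA array: n_copies of the template concatenated,
# with each designated polymorphic site carrying its minor base in
# round(minor_fraction * n_copies) copies (copies shuffled once).
build_rdna_array <- function(template, n_copies, poly_site_rate, n_poly_sites,
                             minor_range, array_id) {
  unit_len <- nchar(template)
  tmpl <- strsplit(template, "")[[1]]
  if (is.null(n_poly_sites)) {
    sites <- which(runif(unit_len) < poly_site_rate)
  } else {
    sites <- sort(sample.int(unit_len, n_poly_sites))
  }
  copies <- matrix(rep(tmpl, n_copies), nrow = unit_len)
  truth <- tibble(template = character(0), pos = integer(0), major_base = character(0),
                  minor_base = character(0), minor_fraction_planned = numeric(0),
                  n_minor_copies = integer(0), minor_fraction_realized = numeric(0))
  if (length(sites) > 0) {
    planned <- runif(length(sites), minor_range[1], minor_range[2])
    minor <- vapply(tmpl[sites], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    character(1), USE.NAMES = FALSE)
    n_minor <- as.integer(round(planned * n_copies))
    for (i in seq_along(sites)) {
      if (n_minor[i] == 0) next
      which_copies <- sample.int(n_copies, n_minor[i])
      copies[sites[i], which_copies] <- minor[i]
    }
    truth <- tibble(template = array_id, pos = sites, major_base = tmpl[sites],
                    minor_base = minor, minor_fraction_planned = planned,
                    n_minor_copies = n_minor,
                    minor_fraction_realized = n_minor / n_copies)
  }
  list(seq = paste(copies, collapse = ""), truth = truth)
}

#' Build a mock genome with ground truth
#'
#' Deterministically instantiates the sequences described by a [genome_spec()]:
#' the plastome is emitted as one circular sequence `LSC + IRa + SSC + IRb`
#' with `IRb` the reverse complement of `IRa`; each rDNA array is a tandem
#' concatenation of its unit copies carrying the planted minor alleles; SSR
#' loci and dispersed repeats are planted at recorded positions in an i.i.d.
#' uniform nuclear background.
#'
#' @param spec A [genome_spec()].
#' @return A list with `genome` (sequence tibble with `circular`,
#'   `compartment` and sampling `weight` columns) and `truth` (list of
#'   ground-truth tables: `poly_sites`, `ssr_loci`, `repeat_pairs`,
#'   `repeat_elements`, `templates`, `expected_read_fractions`, `intervals`).
#' @export
build_mock_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, build_mock_genome_impl(spec))
}

build_mock_genome_impl <- function(spec) {
  p <- spec$plastome
  lsc <- random_dna(p$lsc_len)
  ira <- random_dna(p$ir_len)
  ssc <- random_dna(p$ssc_len)
  plastome <- paste0(lsc, ira, ssc, revcomp(ira))

  mito <- vapply(spec$mito_contig_lengths, random_dna, character(1))

  cis_tmpl <- random_dna(spec$rdna_cistron$unit_len)
  s5_tmpl <- random_dna(spec$rdna_5s$unit_len)
  cis <- build_rdna_array(cis_tmpl, spec$rdna_cistron$n_copies,
                          spec$rdna_cistron$poly_site_rate,
                          spec$rdna_cistron$n_poly_sites,
                          spec$rdna_cistron$minor_copy_fraction_range, "rdna_cistron")
  s5 <- build_rdna_array(s5_tmpl, spec$rdna_5s$n_copies,
                         spec$rdna_5s$poly_site_rate,
                         spec$rdna_5s$n_poly_sites,
                         spec$rdna_5s$minor_copy_fraction_range, "rdna_5s")

  nuc <- strsplit(random_dna(spec$nuclear_length), "")[[1]]

  # plant repeat families then SSRs, non-overlapping, recording positions
  occupied <- integer(0)
  place_span <- function(len) {
    for (i in 1:200) {
      s <- sample.int(spec$nuclear_length - len - 2L, 1) + 1L
      if (!any(seq(s - 1L, s + len) %in% occupied)) {
        occupied <<- c(occupied, seq(s - 1L, s + len))
        return(s)
      }
    }
    abort("could not place a planted feature: plan exceeds nuclear capacity")
  }
  repeat_elements <- tibble(family = character(0), seq = character(0))
  repeat_pairs <- tibble(family = character(0), start = integer(0), end = integer(0))
  if (nrow(spec$repeat_families) > 0) {
    for (i in seq_len(nrow(spec$repeat_families))) {
      fam <- spec$repeat_families$family[i]
      elem <- random_dna(spec$repeat_families$element_length[i])
      repeat_elements <- bind_rows(repeat_elements, tibble(family = fam, seq = elem))
      for (j in seq_len(spec$repeat_families$copy_count[i])) {
        s <- place_span(nchar(elem))
        nuc[s:(s + nchar(elem) - 1L)] <- strsplit(elem, "")[[1]]
        repeat_pairs <- bind_rows(repeat_pairs,
                                  tibble(family = fam, start = s, end = s + nchar(elem) - 1L))
      }
    }
  }
  ssr_loci <- tibble(contig_id = character(0), start = integer(0), end = integer(0),
                     motif = character(0), n_units = integer(0))
  if (nrow(spec$ssr_plan) > 0) {
    for (i in seq_len(nrow(spec$ssr_plan))) {
      motif <- spec$ssr_plan$motif[i]
      units <- spec$ssr_plan$n_units[i]
      run <- strsplit(paste(rep(motif, units), collapse = ""), "")[[1]]
      for (j in seq_len(spec$ssr_plan$count[i])) {
        s <- place_span(length(run))
        nuc[s:(s + length(run) - 1L)] <- run
        # break accidental extension on both flanks
        brk <- setdiff(c("A", "C", "G", "T"), substr(motif, 1, 1))[1]
        nuc[s - 1L] <- brk
        brk2 <- setdiff(c("A", "C", "G", "T"), substr(motif, nchar(motif), nchar(motif)))[1]
        nuc[s + length(run)] <- brk2
        ssr_loci <- bind_rows(ssr_loci,
                              tibble(contig_id = "nuclear", start = s,
                                     end = s + length(run) - 1L,
                                     motif = motif, n_units = units))
      }
    }
  }
  nuclear <- paste(nuc, collapse = "")

  ids <- c("plastome", paste0("mito_", seq_along(mito)), "rdna_cistron_array",
           "rdna_5s_array", if (spec$control_sequence_length > 0) "control", "nuclear")
  seqs <- c(plastome, mito, cis$seq, s5$seq,
            if (spec$control_sequence_length > 0) random_dna(spec$control_sequence_length),
            nuclear)
  comp <- c("chloroplast", rep("mitochondrial", length(mito)), "rdna", "rdna",
            if (spec$control_sequence_length > 0) "control", "nuclear")
  # the control emulates a small circular phage genome (uniform depth)
  circ <- c(TRUE, rep(FALSE, length(mito)), FALSE, FALSE,
            if (spec$control_sequence_length > 0) TRUE, FALSE)
  weight <- c(nchar(plastome) * spec$plastome_copy,
              nchar(mito) * spec$mito_copy,
              nchar(cis$seq), nchar(s5$seq),
              if (spec$control_sequence_length > 0) spec$control_sequence_length,
              spec$nuclear_length)
  genome <- seq_tbl(id = ids, seq = seqs, circular = circ)
  genome$compartment <- comp
  genome$weight <- as.numeric(weight)

  efrac <- genome %>%
    group_by(.data$compartment) %>%
    summarise(weight = sum(.data$weight), .groups = "drop") %>%
    mutate(fraction = .data$weight / sum(.data$weight))

  truth <- list(
    poly_sites = bind_rows(cis$truth, s5$truth),
    ssr_loci = ssr_loci,
    repeat_pairs = repeat_pairs,
    repeat_elements = repeat_elements,
    # unit templates are flagged circular: reads spanning tandem-unit
    # junctions wrap on the unit just as plastome reads wrap at the origin
    templates = seq_tbl(id = c("rdna_cistron", "rdna_5s"), seq = c(cis_tmpl, s5_tmpl),
                        circular = c(TRUE, TRUE)),
    expected_read_fractions = efrac,
    intervals = tibble(id = ids, start = 1L, end = nchar(seqs), compartment = comp),
    spec = spec
  )
  list(genome = genome, truth = truth)
}

#' Read-simulation parameters
#'
#' @param read_length Read length in nt (default 40, the short-read regime
#'   the pipeline is designed for).
#' @param mean_coverage Mean depth over the copy-weighted genome; together
#'   with the genome weights this fixes the read count. Ignored when
#'   `total_bases` is given.
#' @param total_bases Total sequenced bases.
#' @param error_rate Per-base substitution error rate (default 0.004, an
#'   early-instrument raw error magnitude).
#' @param base_quality Constant Phred score emitted for scorable bases.
#' @param frac_n Fraction of reads given one random `N`.
#' @param frac_adapter Fraction of reads whose prefix is replaced by the
#'   adapter sequence.
#' @param adapter Adapter sequence used for contamination.
#' @param frac_b_tail Fraction of reads given an unscorable (Q2) quality tail
#'   starting at a uniform position.
#' @param seed Integer seed for the simulation.
#' @return An object of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 40L, mean_coverage = 0.5, total_bases = NULL,
                            error_rate = 0.004, base_quality = 24L,
                            frac_n = 0, frac_adapter = 0,
                            adapter = "AGATCGGAAGAGCGGTTCAG",
                            frac_b_tail = 0, seed = 1L) {
  stopifnot(read_length >= 4, error_rate >= 0, error_rate < 1,
            frac_n >= 0, frac_n <= 1, frac_adapter >= 0, frac_adapter <= 1,
            frac_b_tail >= 0, frac_b_tail <= 1)
  structure(list(read_length = as.integer(read_length), mean_coverage = mean_coverage,
                 total_bases = total_bases, error_rate = error_rate,
                 base_quality = as.integer(base_quality), frac_n = frac_n,
                 frac_adapter = frac_adapter, adapter = toupper(adapter),
                 frac_b_tail = frac_b_tail, seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Simulate a shotgun read pool from a mock genome
#'
#' Read start positions are uniform over each sequence (wrapping on
#' circular-flagged sequences; truncated at linear ends, minimum 12 nt), the
#' source sequence is chosen proportional to its copy-weighted length so
#' compartment read fractions follow their expectation, substitution errors
#' are drawn per base, and constant-quality Phred strings are emitted with an
#' optional unscorable tail.
#'
#' @param genome Genome tibble from [build_mock_genome()].
#' @param truth Truth list from [build_mock_genome()] (used for provenance
#'   labels); may be `NULL`.
#' @param params A [read_sim_params()].
#' @return A list with `reads` (sequence tibble with qualities) and
#'   `provenance` (read id, source, 1-based start, strand, compartment, QC
#'   flags).
#' @export
simulate_reads <- function(genome, truth, params) {
  stopifnot(inherits(params, "read_sim_params"))
  check_seq_tbl(genome, arg = "genome")
  if (nrow(genome) == 0) abort("`genome` is empty")
  withr::with_seed(params$seed, simulate_reads_impl(genome, truth, params))
}

simulate_reads_impl <- function(genome, truth, params) {
  L <- params$read_length
  lens <- nchar(genome$seq)
  weight <- if ("weight" %in% names(genome)) genome$weight else as.numeric(lens)
  circ <- if ("circular" %in% names(genome)) genome$circular else rep(FALSE, nrow(genome))
  comp <- if ("compartment" %in% names(genome)) genome$compartment else rep(NA_character_, nrow(genome))

  total_bases <- if (!is.null(params$total_bases)) params$total_bases
                 else params$mean_coverage * sum(weight)
  n_reads <- as.integer(ceiling(total_bases / L))
  if (n_reads == 0) {
    warn("requested coverage yields zero reads")
    return(list(reads = seq_tbl(character(0), character(0), qual = list()),
                provenance = tibble()))
  }

  src <- sample.int(nrow(genome), n_reads, replace = TRUE, prob = weight)
  start <- floor(runif(n_reads) * lens[src]) + 1L
  strand <- ifelse(runif(n_reads) < 0.5, "+", "-")

  # extract reads; circular sources wrap via a virtual extension
  ext <- ifelse(circ, paste0(genome$seq, substr(genome$seq, 1L, L - 1L)), genome$seq)
  end_at <- ifelse(circ[src], start + L - 1L, pmin.int(start + L - 1L, lens[src]))
  rl <- end_at - start + 1L
  keep <- rl >= 12L
  src <- src[keep]; start <- start[keep]; strand <- strand[keep]; rl <- rl[keep]
  n_reads <- length(src)
  seqs <- substr(ext[src], start, start + rl - 1L)

  # substitution errors
  if (params$error_rate > 0) {
    tot <- sum(rl)
    err_global <- which(runif(tot) < params$error_rate)
    if (length(err_global) > 0) {
      ends <- cumsum(rl)
      ridx <- findInterval(err_global - 1L, ends) + 1L
      pos_in_read <- err_global - c(0L, ends)[ridx]
      for (i in seq_along(err_global)) {
        r <- ridx[i]; p <- pos_in_read[i]
        old <- substr(seqs[r], p, p)
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        substr(seqs[r], p, p) <- new
      }
    }
  }

  # strand: minus-strand reads are reverse complemented
  neg <- strand == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])

  # adapter contamination
  is_adapter <- runif(n_reads) < params$frac_adapter
  if (any(is_adapter)) {
    alen <- pmin.int(nchar(params$adapter), rl[is_adapter])
    seqs[is_adapter] <- paste0(substr(params$adapter, 1L, alen),
                               substr(seqs[is_adapter], alen + 1L, rl[is_adapter]))
  }

  # N injection
  is_n <- runif(n_reads) < params$frac_n
  if (any(is_n)) {
    idx <- which(is_n)
    p <- floor(runif(length(idx)) * rl[idx]) + 1L
    for (i in seq_along(idx)) substr(seqs[idx[i]], p[i], p[i]) <- "N"
  }

  # qualities: constant, with optional unscorable tails
  tail_start <- rep(NA_integer_, n_reads)
  has_tail <- runif(n_reads) < params$frac_b_tail
  if (any(has_tail)) {
    idx <- which(has_tail)
    tail_start[idx] <- floor(runif(length(idx)) * (rl[idx] - 1L)) + 2L
  }
  qual <- vector("list", n_reads)
  q0 <- params$base_quality
  for (i in seq_len(n_reads)) {
    q <- rep.int(q0, rl[i])
    if (!is.na(tail_start[i])) q[tail_start[i]:rl[i]] <- 2L
    qual[[i]] <- q
  }

  ids <- sprintf("read_%07d", seq_len(n_reads))
  reads <- seq_tbl(id = ids, seq = seqs, qual = qual)
  provenance <- tibble(
    read_id = ids, source = genome$id[src], start = start, strand = strand,
    length = rl, compartment = comp[src],
    is_adapter = is_adapter, has_n = is_n, tail_start = tail_start
  )
  list(reads = reads, provenance = provenance)
}
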