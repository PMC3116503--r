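#' Scan contigs for perfect microsatellites (SSRs)
#'
#' Finds all maximal perfect tandem repeats of 2-6 nt motifs: di- and
#' trinucleotide motifs need at least 4 units, tetra- to hexanucleotide
#' motifs at least 3 (the marker-development rule for short-read contigs).
#' Contigs shorter than `min_contig_len` are skipped so that loci retain
#' flanking sequence for primer design. A run is attributed to its shortest
#' period (motifs that are themselves repetitions of a shorter unit are
#' never reported, which also excludes homopolymers), the reported motif
#' preserves the observed strand and phase, and `motif_canonical` is the
#' lexicographically smallest rotation for class bookkeeping.
#'
#' @param contigs Sequence tibble.
#' @param min_units Named map from motif length ("2".."6") to the minimum
#'   unit count.
#' @param min_contig_len Minimum contig length to scan.
#' @return Tibble: `contig_id`, `start`, `end` (1-based inclusive), `motif`,
#'   `motif_canonical`, `motif_length`, `n_units`.
#' @export
scan_ssrs <- function(contigs,
                      min_units = c("2" = 4L, "3" = 4L, "4" = 3L, "5" = 3L, "6" = 3L),
                      min_contig_len = 150L) {
  check_seq_tbl(contigs, arg = "contigs")
  out <- list()
  for (i in seq_len(nrow(contigs))) {
    s <- contigs$seq[i]
    n <- nchar(s)
    if (n < min_contig_len) next
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in as.integer(names(min_units))) {
      minu <- min_units[[as.character(p)]]
      if (n < p * minu) next
      eq <- x[seq_len(n - p)] == x[seq_len(n - p) + p]
      eq[x[seq_len(n - p)] == "N"] <- FALSE
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        span_len <- r$lengths[j] + p
        units <- span_len %/% p
        if (units < minu) next
        st <- starts[j]
        motif <- substr(s, st, st + p - 1L)
        if (!is_primitive_motif(motif)) next
        out[[length(out) + 1L]] <- tibble(
          contig_id = contigs$id[i],
          start = st, end = st + units * p - 1L,
          motif = motif, motif_canonical = canonical_rotation(motif),
          motif_length = p, n_units = units
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(contig_id = character(0), start = integer(0), end = integer(0),
                  motif = character(0), motif_canonical = character(0),
                  motif_length = integer(0), n_units = integer(0)))
  }
  bind_rows(out) %>% arrange(.data$contig_id, .data$start, .data$motif_length)
}

#' SSR census over a de novo contig set
#'
#' Applies the contig length filter and the SSR scanner, and summarises the
#' yield the way marker-development surveys report it: how many contigs were
#' long enough to scan, how many loci were found, in how many distinct
#' contigs, and the per-motif-class breakdown.
#'
#' @inheritParams scan_ssrs
#' @return A list with `n_contigs_input`, `n_contigs_scanned` (length at
#'   least `min_contig_len`), `loci` (the [scan_ssrs()] tibble), `n_loci`,
#'   `n_contigs_with_loci` and `per_class` (tibble `motif_length`, `n_loci`).
#' @export
ssr_census <- function(contigs,
                       min_units = c("2" = 4L, "3" = 4L, "4" = 3L, "5" = 3L, "6" = 3L),
                       min_contig_len = 150L) {
  check_seq_tbl(contigs, arg = "contigs")
  loci <- scan_ssrs(contigs, min_units, min_contig_len)
  per_class <- loci %>% group_by(.data$motif_length) %>%
    summarise(n_loci = n(), .groups = "drop")
  list(n_contigs_input = nrow(contigs),
       n_contigs_scanned = sum(nchar(contigs$seq) >= min_contig_len),
       loci = loci, n_loci = nrow(loci),
       n_contigs_with_loci = length(unique(loci$contig_id)),
       per_class = per_class)
}

#' PCR-product feasibility of an SSR locus
#'
#' A locus is feasible when some amplicon window inside the contig contains
#' it with at least `min_flank` nt of flank on each side (room for a primer)
#' and a total window length inside `product_range`. No primer design is
#' performed.
#'
#' @param locus One-row tibble from [scan_ssrs()] (`start`, `end`).
#' @param contig_length Length of the contig the locus sits on.
#' @param product_range Allowed amplicon size range (bp).
#' @param min_flank Minimum flank length inside the window (nt).
#' @return Logical flag.
#' @export
ssr_primer_feasibility <- function(locus, contig_length, product_range = c(100L, 450L),
                                   min_flank = 18L) {
  stopifnot(locus$start >= 1, locus$end <= contig_length)
  locus_len <- locus$end - locus$start + 1L
  fl <- locus$start - 1L             # available left flank
  fr <- contig_length - locus$end    # available right flank
  if (fl < min_flank || fr < min_flank) return(FALSE)
  min_window <- locus_len + 2L * min_flank
  max_window <- locus_len + fl + fr
  min_window <= product_range[2] && max_window >= product_range[1]
}

#' Find direct and inverted repeats within a sequence
#'
#' Maximal gapless local self-matches (sequence against itself and against
#' its reverse complement) longer than `min_len` with identity at least
#' `min_identity`. Candidates come from shared exact seeds of length
#' `seed_len`; extension proceeds outward while the running identity stays
#' at or above the threshold, and ends are trimmed back to matching bases.
#' The self-diagonal is excluded and mirrored duplicates are collapsed.
#'
#' @param sequence A single-row sequence tibble, or a single string.
#' @param min_len Minimum repeat length; strictly greater-than by default
#'   (`inclusive = FALSE`), matching the "greater than 30 bp" reading.
#' @param min_identity Minimum identity.
#' @param kinds Subset of `c("direct", "inverted")`.
#' @param seed_len Exact seed length used to find candidates.
#' @param inclusive If `TRUE`, repeats of exactly `min_len` are kept too.
#' @return Tibble: `kind`, `start_a`, `end_a`, `start_b`, `end_b` (1-based
#'   inclusive, span_a before span_b), `length`, `matches`, `identity`.
#' @export
find_repeats <- function(sequence, min_len = 30L, min_identity = 0.85,
                         kinds = c("direct", "inverted"), seed_len = 12L,
                         inclusive = FALSE) {
  if (is.data.frame(sequence)) {
    check_seq_tbl(sequence, arg = "sequence")
    stopifnot(nrow(sequence) == 1)
    s <- sequence$seq[[1]]
  } else {
    s <- normalize_bases(toupper(sequence))
  }
  n <- nchar(s)
  if (n < 2 * min_len) abort("sequence shorter than twice `min_len`")
  kinds <- match.arg(kinds, several.ok = TRUE)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  res <- list()
  if ("direct" %in% kinds) {
    res <- c(res, repeat_pairs_one(x, x, "direct", min_len, min_identity,
                                   seed_len, inclusive, exclude_self = TRUE))
  }
  if ("inverted" %in% kinds) {
    y <- strsplit(revcomp(s), "", fixed = TRUE)[[1]]
    res <- c(res, repeat_pairs_one(x, y, "inverted", min_len, min_identity,
                                   seed_len, inclusive, exclude_self = FALSE))
  }
  if (length(res) == 0) {
    return(tibble(kind = character(0), start_a = integer(0), end_a = integer(0),
                  start_b = integer(0), end_b = integer(0), length = integer(0),
                  matches = integer(0), identity = numeric(0)))
  }
  out <- bind_rows(res)
  out <- out[!duplicated(out[, c("kind", "start_a", "end_a", "start_b", "end_b")]), ]
  arrange(out, .data$kind, .data$start_a, .data$start_b)
}

# Seed-and-extend local matches between character vectors a and b.
# For "inverted", b is revcomp(sequence): a match a[i..i+l-1] == b[j..j+l-1]
# corresponds to sequence spans [i, i+l-1] and [n-(j+l-1)+1, n-j+1].
repeat_pairs_one <- function(a, b, kind, min_len, min_identity, seed_len,
                             inclusive, exclude_self) {
  n <- length(a)
  sa <- paste(a, collapse = "")
  sb <- paste(b, collapse = "")
  ka <- substring(sa, seq_len(n - seed_len + 1L), seq_len(n - seed_len + 1L) + seed_len - 1L)
  kb <- if (identical(sa, sb)) ka else
    substring(sb, seq_len(n - seed_len + 1L), seq_len(n - seed_len + 1L) + seed_len - 1L)
  ka_clean <- !grepl("N", ka, fixed = TRUE)
  kb_clean <- !grepl("N", kb, fixed = TRUE)
  ib <- split(which(kb_clean), kb[kb_clean])
  seeds_i <- integer(0); seeds_j <- integer(0)
  for (i in which(ka_clean)) {
    js <- ib[[ka[i]]]
    if (!is.null(js)) {
      seeds_i <- c(seeds_i, rep.int(i, length(js)))
      seeds_j <- c(seeds_j, js)
    }
  }
  if (length(seeds_i) == 0) return(list())
  if (exclude_self) {
    keep <- seeds_i < seeds_j  # one triangle; mirrors collapse automatically
    seeds_i <- seeds_i[keep]; seeds_j <- seeds_j[keep]
  }
  if (length(seeds_i) == 0) return(list())
  # cluster seeds on the same diagonal
  diag <- seeds_j - seeds_i
  ord <- order(diag, seeds_i)
  seeds_i <- seeds_i[ord]; seeds_j <- seeds_j[ord]; diag <- diag[ord]
  new_cluster <- c(TRUE, diff(diag) != 0 | diff(seeds_i) > seed_len)
  cl <- cumsum(new_cluster)
  out <- list()
  seen <- character(0)
  for (g in split(seq_along(cl), cl)) {
    i0 <- seeds_i[g[1]]; j0 <- seeds_j[g[1]]
    i1 <- seeds_i[g[length(g)]] + seed_len - 1L
    ext <- extend_match(a, b, i0, j0, i1 - i0 + 1L, min_identity)
    if (is.null(ext)) next
    len <- ext$len
    qual_len <- if (inclusive) len >= min_len else len > min_len
    if (!qual_len || ext$matches / len < min_identity) next
    ia <- ext$i; ja <- ext$j
    if (kind == "direct") {
      s_a <- c(ia, ia + len - 1L); s_b <- c(ja, ja + len - 1L)
    } else {
      s_a <- c(ia, ia + len - 1L)
      s_b <- c(n - (ja + len - 1L) + 1L, n - ja + 1L)
    }
    spans <- rbind(s_a, s_b)
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    if (kind == "inverted" && all(spans[1, ] == spans[2, ])) next  # self palindrome
    key <- paste(kind, spans[1, 1], spans[1, 2], spans[2, 1], spans[2, 2])
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- tibble(
      kind = kind, start_a = spans[1, 1], end_a = spans[1, 2],
      start_b = spans[2, 1], end_b = spans[2, 2],
      length = len, matches = ext$matches, identity = ext$matches / len
    )
  }
  out
}

# X-drop outward extension from a seed core. Scoring: match +1, mismatch
# -min_identity/(1-min_identity), so a segment scores >= 0 exactly when its
# identity reaches the threshold; each side stops at its best-scoring
# endpoint (ends therefore always sit on matches). Returns NULL when the
# extended segment is empty.
extend_match <- function(a, b, i, j, core_len, min_identity) {
  n_a <- length(a); n_b <- length(b)
  lambda <- min_identity / (1 - min_identity + 1e-9)
  xdrop <- 3 * lambda + 10
  step_score <- function(m) if (m) 1 else -lambda

  # right of the core start: scan from i (inclusive) forward
  best_right <- -1L  # offset of best end relative to i
  score <- 0; best <- -Inf
  off <- 0L
  while (i + off <= n_a && j + off <= n_b) {
    m <- a[i + off] == b[j + off] && a[i + off] != "N"
    score <- score + step_score(m)
    if (score > best) { best <- score; best_right <- off }
    if (score < best - xdrop) break
    off <- off + 1L
  }
  if (best_right < 0L) return(NULL)
  # left of the core start
  best_left <- 0L
  score <- 0; best <- 0
  off <- 1L
  while (i - off >= 1L && j - off >= 1L) {
    m <- a[i - off] == b[j - off] && a[i - off] != "N"
    score <- score + step_score(m)
    if (score > best) { best <- score; best_left <- off }
    if (score < best - xdrop) break
    off <- off + 1L
  }
  i2 <- i - best_left; j2 <- j - best_left
  len <- best_right + best_left + 1L
  # trim any non-matching ends (possible when core start itself mismatched)
  while (len > 0L && !(a[i2] == b[j2] && a[i2] != "N")) {
    i2 <- i2 + 1L; j2 <- j2 + 1L; len <- len - 1L
  }
  while (len > 0L && !(a[i2 + len - 1L] == b[j2 + len - 1L] && a[i2 + len - 1L] != "N")) {
    len <- len - 1L
  }
  if (len == 0L) return(NULL)
  matches <- sum(a[i2:(i2 + len - 1L)] == b[j2:(j2 + len - 1L)] & a[i2:(i2 + len - 1L)] != "N")
  list(i = i2, j = j2, len = len, matches = matches)
}

#' Resolve the quadripartite structure of a plastome
#'
#' The longest inverted self-match with identity at least `ir_min_identity`
#' and length at least `ir_min_len` defines the two inverted-repeat arms
#' (IRa/IRb); the two remaining arcs of the circle are the large and small
#' single-copy regions (LSC the longer, SSC the shorter).
#'
#' @param plastome Single-row sequence tibble (circular).
#' @param ir_min_len Minimum IR length to accept (bp).
#' @param ir_min_identity Minimum IR arm identity.
#' @return A list with `has_ir` and, when an IR is found, `ir_len`,
#'   `lsc_len`, `ssc_len` and `boundaries` (tibble of the two IR spans);
#'   `lsc_len + 2 * ir_len + ssc_len` equals the genome length.
#' @export
detect_quadripartite <- function(plastome, ir_min_len = 1000L, ir_min_identity = 0.99) {
  check_seq_tbl(plastome, arg = "plastome")
  stopifnot(nrow(plastome) == 1)
  n <- nchar(plastome$seq[[1]])
  rp <- find_repeats(plastome, min_len = ir_min_len, min_identity = ir_min_identity,
                     kinds = "inverted", inclusive = TRUE)
  if (nrow(rp) == 0) return(list(has_ir = FALSE, genome_length = n))
  best <- rp[which.max(rp$length), ]
  ir_len <- best$length
  gap_inner <- best$start_b - best$end_a - 1L
  gap_outer <- n - best$end_b + best$start_a - 1L
  list(has_ir = TRUE, genome_length = n, ir_len = ir_len,
       lsc_len = max(gap_inner, gap_outer), ssc_len = min(gap_inner, gap_outer),
       ir_identity = best$identity,
       boundaries = tibble(arm = c("IRa", "IRb"),
                           start = c(best$start_a, best$start_b),
                           end = c(best$end_a, best$end_b)))
}

#' Classify queries against a repeat library
#'
#' Each query (read or contig) counts once when it has at least one
#' qualifying placement on any library element; per-family counts use the
#' library's family labels (a `family` column, or a `"family:"` prefix on
#' the element ids).
#'
#' @param queries Sequence tibble of reads or contigs.
#' @param library Sequence tibble of repeat elements.
#' @param seed_len Seed length for placement.
#' @param min_identity Minimum identity (default 0.70, the permissive
#'   repeat-census setting).
#' @param seed_stride Seed spacing passed to [place_reads()].
#' @return A list with `fraction_with_hit`, `n_with_hit`, `n_queries` and
#'   `per_family` (tibble `family`, `n_queries`).
#' @export
classify_vs_repeat_library <- function(queries, library, seed_len = 11L,
                                       min_identity = 0.70, seed_stride = 1L) {
  check_seq_tbl(queries, arg = "queries")
  check_seq_tbl(library, arg = "library")
  if (nrow(library) == 0) abort("`library` is empty")
  fam <- if ("family" %in% names(library)) library$family
         else sub("^family:([^ _]+).*$", "\\1", library$id)
  hit_family <- rep(NA_character_, nrow(queries))
  for (i in seq_len(nrow(library))) {
    todo <- which(is.na(hit_family))
    if (length(todo) == 0) break
    pl <- place_reads(queries[todo, , drop = FALSE], library[i, , drop = FALSE],
                      seed_len = seed_len, min_identity = min_identity,
                      max_hits_per_read = 1L, seed_stride = seed_stride)
    hit_family[todo[queries$id[todo] %in% pl$read_id]] <- fam[i]
  }
  n_hit <- sum(!is.na(hit_family))
  per_family <- tibble(family = hit_family[!is.na(hit_family)]) %>%
    group_by(.data$family) %>% summarise(n_queries = n(), .groups = "drop")
  list(fraction_with_hit = n_hit / nrow(queries), n_with_hit = n_hit,
       n_queries = nrow(queries), per_family = per_family)
}

#' Pairwise identity with gapped columns removed
#'
#' Columns containing a gap character in either aligned sequence are removed
#' before identity is computed as matches over the remaining columns.
#'
#' @param aligned_a,aligned_b Equal-length aligned sequences (strings).
#' @param gap_chars Characters treated as gaps.
#' @return Identity as a proportion.
#' @export
pairwise_identity <- function(aligned_a, aligned_b, gap_chars = c("-", ".")) {
  stopifnot(is.character(aligned_a), is.character(aligned_b),
            length(aligned_a) == 1, length(aligned_b) == 1)
  if (nchar(aligned_a) != nchar(aligned_b)) {
    abort("aligned sequences must have equal length")
  }
  a <- strsplit(toupper(aligned_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(aligned_b), "", fixed = TRUE)[[1]]
  keep <- !(a %in% gap_chars) & !(b %in% gap_chars)
  if (!any(keep)) abort("no ungapped columns: identity undefined")
  sum(a[keep] == b[keep]) / sum(keep)
}
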