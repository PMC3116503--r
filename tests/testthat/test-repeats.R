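test_that("SSR rule boundaries behave as specified", {
  withr::with_seed(121, flank <- random_dna(80))
  # (TA)6 with ample flanks: one dinucleotide locus
  ctg <- seq_tbl("c1", paste0(flank, "C", strrep("TA", 6), "G", flank))
  loci <- scan_ssrs(ctg)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$motif, "TA")
  expect_equal(loci$motif_canonical, "AT")
  expect_equal(loci$n_units, 6L)
  # (AGG)3 is below the trinucleotide minimum of 4 units
  ctg2 <- seq_tbl("c2", paste0(flank, "C", strrep("AGG", 3), "T", flank))
  expect_equal(nrow(scan_ssrs(ctg2)), 0L)
  # (ATTC)3 meets the tetranucleotide minimum of 3
  ctg3 <- seq_tbl("c3", paste0(flank, "G", strrep("ATTC", 3), "G", flank))
  expect_equal(scan_ssrs(ctg3)$n_units, 3L)
  # homopolymers are never dinucleotide loci
  ctg4 <- seq_tbl("c4", paste0(flank, "C", strrep("A", 12), "C", flank))
  expect_equal(nrow(scan_ssrs(ctg4)), 0L)
  # short contigs are skipped
  ctg5 <- seq_tbl("c5", paste0("C", strrep("TA", 6), "G"))
  expect_equal(nrow(scan_ssrs(ctg5)), 0L)
})

test_that("the scanner equals the regex oracle on random sequences", {
  withr::with_seed(122, {
    for (i in 1:10) {
      s <- random_dna(3000)
      # spike a couple of loci so non-trivial cases always occur
      s <- paste0(s, "C", strrep("TC", 5), "A", strrep("TAA", 4), "C", random_dna(200))
      got <- scan_ssrs(seq_tbl("c", s))
      want <- oracle_ssr_regex(s)
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$motif, want$motif)
      expect_equal(got$n_units, want$n_units)
    }
  })
})

test_that("SSR output is invariant to contig order and the census adds up", {
  withr::with_seed(123, {
    ctgs <- seq_tbl(sprintf("c%02d", 1:20),
                    vapply(sample(c(80, 200, 400), 20, TRUE), random_dna, character(1)))
  })
  ctgs$seq[3] <- paste0(ctgs$seq[3], "G", strrep("AT", 8))
  a <- scan_ssrs(ctgs)
  b <- scan_ssrs(ctgs[sample(nrow(ctgs)), ]) %>% dplyr::arrange(contig_id, start, motif_length)
  expect_equal(a, dplyr::arrange(b, contig_id, start, motif_length))
  cen <- ssr_census(ctgs)
  expect_equal(cen$n_contigs_scanned, sum(nchar(ctgs$seq) >= 150))
  expect_equal(cen$n_loci, nrow(cen$loci))
  expect_equal(sum(cen$per_class$n_loci), cen$n_loci)
})

test_that("primer feasibility matches a brute-force window search", {
  brute <- function(start, end, clen, range = c(100, 450), flank = 18) {
    if (start - flank < 1 || end + flank > clen) return(FALSE)
    for (w1 in seq_len(start - flank)) {
      w_min <- (end + flank) - w1 + 1
      w_max <- clen - w1 + 1
      if (w_min <= range[2] && w_max >= range[1]) return(TRUE)
    }
    FALSE
  }
  # centred locus in a 150 bp contig is feasible; 5 bp from the end is not
  loc <- tibble::tibble(start = 70L, end = 81L)
  expect_true(ssr_primer_feasibility(loc, 150L))
  loc2 <- tibble::tibble(start = 134L, end = 145L)
  expect_false(ssr_primer_feasibility(loc2, 150L))
  withr::with_seed(124, {
    for (i in 1:100) {
      clen <- sample(60:600, 1)
      st <- sample(seq_len(clen - 12L), 1)
      en <- min(clen, st + sample(8:40, 1))
      loc <- tibble::tibble(start = st, end = en)
      expect_equal(ssr_primer_feasibility(loc, clen), brute(st, en, clen),
                   info = sprintf("clen=%d st=%d en=%d", clen, st, en))
    }
  })
})

test_that("planted exact repeats are found at full length and identity", {
  withr::with_seed(125, {
    bg <- random_dna(4000)
    dr <- random_dna(66)
    iv <- random_dna(32)
  })
  s <- paste0(substr(bg, 1, 500), dr, substr(bg, 501, 1800), dr,
              substr(bg, 1801, 2600), iv, substr(bg, 2601, 3300), revcomp(iv),
              substr(bg, 3301, 4000))
  fr <- find_repeats(seq_tbl("s", s), min_len = 30, min_identity = 0.85)
  direct <- fr[fr$kind == "direct", ]
  inv <- fr[fr$kind == "inverted", ]
  expect_equal(nrow(direct), 1L)
  expect_gte(direct$length, 66L)
  expect_equal(direct$identity, 1)
  expect_equal(nrow(inv), 1L)
  expect_gte(inv$length, 32L)
  expect_equal(inv$identity, 1)
  # the planted spans are inside the reported ones
  expect_lte(direct$start_a, 501L); expect_gte(direct$end_a, 566L)
  # "greater than 30 bp" is strict: an exact 30-mer pair is not reported
  withr::with_seed(126, {
    bg2 <- random_dna(2000); r30 <- random_dna(30)
  })
  s2 <- paste0(substr(bg2, 1, 400), r30, substr(bg2, 401, 1400), r30,
               substr(bg2, 1401, 2000))
  fr2 <- find_repeats(seq_tbl("s", s2), min_len = 30, min_identity = 0.9)
  expect_false(any(fr2$kind == "direct" & fr2$identity == 1 & fr2$length == 30))
  fr2i <- find_repeats(seq_tbl("s", s2), min_len = 30, min_identity = 0.9,
                       inclusive = TRUE)
  expect_true(any(fr2i$kind == "direct" & fr2i$length >= 30))
})

test_that("exact repeat sets match the diagonal-scan oracle on small sequences", {
  withr::with_seed(127, {
    for (i in 1:5) {
      bg <- random_dna(700)
      r1 <- random_dna(45)
      s <- paste0(substr(bg, 1, 150), r1, substr(bg, 151, 420), r1,
                  substr(bg, 421, 560), revcomp(r1), substr(bg, 561, 700))
      got <- find_repeats(seq_tbl("x", s), min_len = 40, min_identity = 0.99)
      for (kind in c("direct", "inverted")) {
        want <- oracle_exact_repeats(s, 40, kind)
        g <- got[got$kind == kind & got$identity == 1, ]
        expect_equal(nrow(g), nrow(want), info = kind)
        if (nrow(want) > 0) {
          expect_true(all(paste(g$start_a, g$end_a, g$start_b, g$end_b) %in%
                            paste(want$start_a, want$end_a, want$start_b, want$end_b)),
                      info = kind)
        }
      }
    }
  })
})

test_that("repeat finding commutes with reverse complement", {
  withr::with_seed(128, {
    bg <- random_dna(1500); dr <- random_dna(50)
  })
  s <- paste0(substr(bg, 1, 300), dr, substr(bg, 301, 900), dr, substr(bg, 901, 1500))
  n <- nchar(s)
  a <- find_repeats(seq_tbl("s", s), min_len = 40, min_identity = 0.9)
  b <- find_repeats(seq_tbl("s", revcomp(s)), min_len = 40, min_identity = 0.9)
  reflect <- function(d, n) {
    ra <- cbind(n - d$end_b + 1L, n - d$start_b + 1L)
    rb <- cbind(n - d$end_a + 1L, n - d$start_a + 1L)
    sort(paste(d$kind, ra[, 1], ra[, 2], rb[, 1], rb[, 2]))
  }
  expect_equal(sort(paste(a$kind, a$start_a, a$end_a, a$start_b, a$end_b)),
               reflect(b, n))
})

test_that("quadripartite structure is recovered exactly by construction", {
  withr::with_seed(129, {
    lsc <- random_dna(2000); ir <- random_dna(300); ssc <- random_dna(400)
  })
  # pin the inner SSC boundary bases so the planted IR cannot extend by a
  # chance complementary match across the junction
  ssc <- paste0("A", substr(ssc, 2, 399), "A")
  pl <- seq_tbl("p", paste0(lsc, ir, ssc, revcomp(ir)), circular = TRUE)
  q <- detect_quadripartite(pl, ir_min_len = 100)
  expect_true(q$has_ir)
  expect_equal(q$ir_len, 300L)
  expect_equal(q$lsc_len, 2000L)
  expect_equal(q$ssc_len, 400L)
  expect_equal(q$lsc_len + 2 * q$ir_len + q$ssc_len, q$genome_length)
  # no planted IR: reported as such, not an error
  withr::with_seed(130, noir <- seq_tbl("p", random_dna(3000), circular = TRUE))
  expect_false(detect_quadripartite(noir, ir_min_len = 100)$has_ir)
})

test_that("repeat-library classification counts each query once", {
  withr::with_seed(131, {
    lib <- seq_tbl(c("family:copia elem1", "family:gypsy elem2"),
                   c(random_dna(200), random_dna(180)))
    bg_reads <- seq_tbl(sprintf("b%02d", 1:20),
                        vapply(rep(40, 20), random_dna, character(1)))
  })
  q1 <- seq_tbl("hit1", substr(lib$seq[1], 50, 89))
  res <- classify_vs_repeat_library(dplyr::bind_rows(q1, bg_reads), lib)
  expect_equal(res$n_with_hit, 1L)
  expect_equal(res$fraction_with_hit, 1 / 21)
  expect_equal(res$per_family$family, "copia")
  # a 60%-identity query does not qualify at the 70% threshold
  withr::with_seed(132, {
    far <- strsplit(substr(lib$seq[1], 50, 89), "")[[1]]
    flip <- sample(40, 16)
    far[flip] <- vapply(far[flip], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  })
  res2 <- classify_vs_repeat_library(seq_tbl("far", paste(far, collapse = "")), lib)
  expect_equal(res2$n_with_hit, 0L)
})

test_that("planted library-derived reads are recovered from simulator truth", {
  sp <- small_skim_spec(seed = 133)
  sp$repeat_families <- tibble::tibble(family = "copia_like",
                                       element_length = 300L, copy_count = 5L)
  g <- build_mock_genome(sp)
  pr <- read_sim_params(total_bases = 2e5, error_rate = 0, seed = 134)
  sim <- simulate_reads(g$genome, g$truth, pr)
  lib <- g$truth$repeat_elements
  lib$id <- paste0("family:", lib$family)
  res <- classify_vs_repeat_library(sim$reads, lib[, c("id", "seq", "family")])
  hits <- res$n_with_hit
  # every error-free read lying wholly inside a planted copy must hit
  pv <- sim$provenance
  inside <- rep(FALSE, nrow(pv))
  rp <- g$truth$repeat_pairs
  nuc <- pv$source == "nuclear"
  for (i in seq_len(nrow(rp))) {
    inside <- inside | (nuc & pv$start >= rp$start[i] &
                          pv$start + pv$length - 1L <= rp$end[i])
  }
  pl_hits <- classify_vs_repeat_library(sim$reads[inside, , drop = FALSE],
                                        lib[, c("id", "seq", "family")])
  expect_equal(pl_hits$n_with_hit, sum(inside))
  # and reads from the plastome never hit the nuclear repeat library
  chl <- pv$compartment == "chloroplast"
  pl_chl <- classify_vs_repeat_library(sim$reads[chl, , drop = FALSE],
                                       lib[, c("id", "seq", "family")])
  expect_equal(pl_chl$n_with_hit, 0L)
  expect_gte(hits, sum(inside))
})

test_that("pairwise identity drops gapped columns", {
  expect_equal(pairwise_identity("AC-GT", "ACTGT"), 1)
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  expect_error(pairwise_identity("ACG", "ACGT"), "equal length")
  expect_error(pairwise_identity("----", "ACGT"), "undefined")
  withr::with_seed(135, {
    for (i in 1:50) {
      n <- sample(10:60, 1)
      a <- sample(c("A", "C", "G", "T", "-"), n, TRUE, prob = c(rep(0.22, 4), 0.12))
      b <- sample(c("A", "C", "G", "T", "-"), n, TRUE, prob = c(rep(0.22, 4), 0.12))
      keep <- a != "-" & b != "-"
      if (!any(keep)) next
      expect_equal(pairwise_identity(paste(a, collapse = ""), paste(b, collapse = "")),
                   sum(a[keep] == b[keep]) / sum(keep))
    }
  })
})
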