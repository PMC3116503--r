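test_that("exact and reverse-complement substrings place correctly", {
  withr::with_seed(71, ref <- seq_tbl("ref", random_dna(2000)))
  rd <- seq_tbl(c("fwd", "rev"),
                c(substr(ref$seq, 101, 140), revcomp(substr(ref$seq, 501, 540))))
  pl <- place_reads(rd, ref)
  expect_equal(pl$ref_start, c(101L, 501L))
  expect_equal(pl$strand, c("+", "-"))
  expect_equal(pl$identity, c(1, 1))
  expect_error(place_reads(rd, ref, seed_len = 3), "degenerate")
})

test_that("placements agree with the exhaustive alignment oracle", {
  withr::with_seed(72, {
    ref <- seq_tbl("ref", random_dna(600))
    n <- 60
    starts <- sample(600 - 39, n, replace = TRUE)
    seqs <- substring(ref$seq, starts, starts + 39)
    # up to 2 substitutions per read: the stride-1 seed guarantee holds
    nerr <- sample(0:2, n, replace = TRUE)
    for (i in seq_len(n)) {
      if (nerr[i] == 0) next
      p <- sample(40, nerr[i])
      s <- strsplit(seqs[i], "")[[1]]
      s[p] <- vapply(s[p], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      seqs[i] <- paste(s, collapse = "")
    }
    flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
    seqs[flip] <- revcomp(seqs[flip])
    reads <- seq_tbl(sprintf("r%02d", 1:n), seqs)
  })
  pl <- place_reads(reads, ref, seed_len = 11, min_identity = 0.85)
  for (i in seq_len(nrow(reads))) {
    o <- oracle_align_best(reads$seq[i], ref$seq, 0.85)
    mine <- pl[pl$read_id == reads$id[i], ]
    expect_equal(nrow(mine), 1L, info = reads$id[i])
    expect_equal(mine$ref_start, o$start, info = reads$id[i])
    expect_equal(mine$strand, o$strand, info = reads$id[i])
    expect_equal(mine$matches, o$matches, info = reads$id[i])
  }
})

test_that("error-free simulated reads recover their provenance", {
  sp <- small_skim_spec(seed = 73)
  g <- build_mock_genome(sp)
  mito <- g$genome[g$genome$id == "mito_1", ]
  pr <- read_sim_params(total_bases = 10 * nchar(mito$seq), error_rate = 0, seed = 74)
  sim <- simulate_reads(mito, NULL, pr)
  pl <- place_reads(sim$reads, mito)
  m <- match(pl$read_id, sim$provenance$read_id)
  agree <- pl$ref_start == sim$provenance$start[m] & pl$strand == sim$provenance$strand[m]
  expect_gte(mean(agree), 0.99)
  expect_gte(nrow(pl) / nrow(sim$reads), 0.99)
})

test_that("pileup accounting is exact", {
  withr::with_seed(75, ref <- seq_tbl("ref", random_dna(300)))
  rd <- seq_tbl(c("a", "b"),
                c(substr(ref$seq, 1, 40), substr(ref$seq, 21, 60)))
  pl <- place_reads(rd, ref)
  pu <- build_pileup(pl, rd, ref)
  expect_equal(sum(pu$depth), sum(pl$aligned_length))
  expect_equal(max(pu$depth), 2L)
  expect_equal(sum(pu$depth == 2L), 20L)

  # two reads disagreeing at one site give two non-zero counts summing to 2
  v <- rd
  s <- strsplit(v$seq[2], "")[[1]]
  s[1] <- setdiff(c("A", "C", "G", "T"), s[1])[1]
  v$seq[2] <- paste(s, collapse = "")
  pl2 <- place_reads(v, ref)
  pu2 <- build_pileup(pl2, v, ref)
  col <- pu2[pu2$pos == 21, c("a", "c", "g", "t")]
  expect_equal(sum(col > 0), 2)
  expect_equal(sum(col), 2)

  # an N read base lands in the N count but still in depth
  s[2] <- "N"
  v$seq[2] <- paste(s, collapse = "")
  pl3 <- place_reads(v, ref)
  pu3 <- build_pileup(pl3, v, ref)
  expect_equal(pu3$n[pu3$pos == 22], 1L)
  expect_equal(sum(pu3$depth), sum(pl3$aligned_length))

  # placements overrunning a linear reference are rejected
  bad <- pl
  bad$ref_start <- 290L
  expect_error(build_pileup(bad, rd, ref), "overrun")
})

test_that("deep pileup depths match a direct recount from provenance", {
  sp <- small_skim_spec(seed = 76)
  g <- build_mock_genome(sp)
  ctrl <- g$genome[g$genome$id == "control", ]
  pr <- read_sim_params(total_bases = 100 * nchar(ctrl$seq), error_rate = 0, seed = 77)
  sim <- simulate_reads(ctrl, NULL, pr)
  pl <- place_reads(sim$reads, ctrl)
  pu <- build_pileup(pl, sim$reads, ctrl)
  # brute-force recount from the provenance table (circular source: wrap)
  L <- nchar(ctrl$seq)
  depth <- integer(L)
  pv <- sim$provenance[sim$provenance$read_id %in% pl$read_id, ]
  for (i in seq_len(nrow(pv))) {
    span <- ((pv$start[i]:(pv$start[i] + pv$length[i] - 1L) - 1L) %% L) + 1L
    depth[span] <- depth[span] + 1L
  }
  expect_equal(pu$depth, depth)
})

test_that("consensus calls and masks follow the policy", {
  # {A:10} with (min_depth 3, min_major 0.7) calls A
  pu <- tibble::tibble(ref_id = "r", pos = 1:3,
                       a = c(10L, 6L, 0L), c = 0L, g = c(0L, 4L, 0L), t = 0L,
                       n = 0L, depth = c(10L, 10L, 0L))
  cc <- call_consensus(pu, mask_policy(min_depth = 3, min_major_proportion = 0.7,
                                       snp_min_minor_proportion = 0.2))
  expect_equal(cc$columns$consensus_base[1], "A")
  # {A:6, G:4}: minor proportion 0.4 >= 0.2 masks the SNP position
  expect_equal(cc$columns$consensus_base[2], "N")
  # zero-depth positions split contigs
  expect_equal(nrow(cc$contigs), 1L)
  expect_equal(cc$contigs$end, 2L)

  # IUPAC mode codes the SNP instead (majority bar lowered so the 60/40
  # column is not depth/proportion-masked first)
  cc2 <- call_consensus(pu, mask_policy(min_major_proportion = 0.5,
                                        snp_mask_mode = "IUPAC"))
  expect_equal(cc2$columns$consensus_base[2], "R")

  # masking is monotone: raising min_major_proportion never unmasks
  withr::with_seed(78, {
    pu2 <- tibble::tibble(ref_id = "r", pos = 1:200,
                          a = sample(0:12, 200, TRUE), c = sample(0:4, 200, TRUE),
                          g = sample(0:4, 200, TRUE), t = sample(0:2, 200, TRUE),
                          n = 0L)
    pu2$depth <- as.integer(pu2$a + pu2$c + pu2$g + pu2$t)
  })
  props <- seq(0.5, 0.95, by = 0.05)
  masks <- lapply(props, function(p) {
    call_consensus(pu2, mask_policy(min_major_proportion = p,
                                    snp_mask_mode = "off"))$columns$masked
  })
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i + 1]][masks[[i]]]))
  }
})

test_that("error-free deep consensus reproduces a non-repetitive template", {
  sp <- small_skim_spec(seed = 79)
  g <- build_mock_genome(sp)
  mito <- g$genome[g$genome$id == "mito_2", ]
  pr <- read_sim_params(total_bases = 120 * nchar(mito$seq), error_rate = 0, seed = 80)
  sim <- simulate_reads(mito, NULL, pr)
  pl <- place_reads(sim$reads, mito)
  pu <- build_pileup(pl, sim$reads, mito)
  cc <- call_consensus(pu, mask_policy())
  expect_equal(nrow(cc$contigs), 1L)
  # end effects excluded: the outermost read-length of a linear reference can
  # fall below min_depth at skim-style uniform starts
  L <- nchar(mito$seq)
  interior <- 41:(L - 40)
  expect_equal(substr(cc$contigs$sequence, 41, L - 40),
               substr(mito$seq, 41, L - 40))
  expect_false(any(cc$columns$masked[interior]))
})

test_that("assembly statistics match their definitions", {
  mk <- function(lens) {
    tibble::tibble(ref_id = "r", start = 1L, end = lens, length = lens,
                   sequence = strrep("A", lens), median_depth = 1)
  }
  pu1 <- tibble::tibble(ref_id = "r", pos = 1:10, a = 32L, c = 0L, g = 0L, t = 0L,
                        n = 0L, depth = 32L)
  st <- assembly_stats(mk(c(5L, 4L, 3L, 2L)), pu1)
  expect_equal(st$n50, 4L)  # cumulative 5, 9 >= 7
  expect_equal(st$longest, 5L)
  expect_equal(st$median_depth, 32)
  st1 <- assembly_stats(mk(100L), pu1)
  expect_equal(st1$n50, 100L)
  expect_error(assembly_stats(mk(integer(0)), pu1), "no contigs")

  # N50 equals the brute-force definition on random contig sets
  withr::with_seed(81, {
    for (i in 1:50) {
      lens <- sample(1:5000, sample(2:40, 1), replace = TRUE)
      expect_equal(assembly_stats(mk(lens), pu1)$n50, oracle_n50(lens))
    }
  })
})
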