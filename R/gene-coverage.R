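#' Count unique read hits per gene
#'
#' A hit is a qualifying placement of a read on a gene; each read is counted
#' at most once per gene regardless of how many places it hits within that
#' gene, while one read may hit several genes. Soft-masked (lower-case)
#' regions of the gene references are excluded from seeding.
#'
#' @param reads Sequence tibble.
#' @param genes Sequence tibble of gene references (soft masking honoured).
#' @param seed_len Seed length (default 7, the short-seed setting for
#'   divergent-gene matching).
#' @param min_identity Minimum identity (default 0.80).
#' @param seed_stride Seed spacing passed to [place_reads()].
#' @return Tibble: `gene_id`, `gene_length`, `n_unique_hits`.
#' @export
count_unique_hits <- function(reads, genes, seed_len = 7L, min_identity = 0.80,
                              seed_stride = 1L) {
  check_seq_tbl(reads)
  check_seq_tbl(genes, arg = "genes")
  if (nrow(genes) == 0) abort("`genes` is empty")
  counts <- vapply(seq_len(nrow(genes)), function(i) {
    pl <- place_reads(reads, genes[i, , drop = FALSE], seed_len = seed_len,
                      min_identity = min_identity, max_hits_per_read = 1L,
                      seed_stride = seed_stride, honor_softmask = TRUE)
    length(unique(pl$read_id))
  }, integer(1))
  tibble(gene_id = genes$id, gene_length = nchar(genes$seq), n_unique_hits = counts)
}

#' Gene coverage from unique hit counts
#'
#' Hits per kilobase is `n_hits / (gene_length / 1000)`; the per-gene
#' coverage estimate is `(hits per kb * read length) / 1000`. Both are also
#' reported rounded to two decimals. Coverage is overestimated when reads
#' overlap (e.g. PCR duplicates).
#'
#' @param n_hits Unique hit count(s).
#' @param gene_length Gene length(s) in bp.
#' @param read_length Read length in nt.
#' @return Tibble: `n_hits`, `gene_length`, `read_length`, `hits_per_kb`,
#'   `coverage`, `hits_per_kb_rounded`, `coverage_rounded`.
#' @export
coverage_from_hits <- function(n_hits, gene_length, read_length) {
  if (any(gene_length <= 0)) abort("`gene_length` must be positive")
  hpk <- n_hits / (gene_length / 1000)
  cov <- hpk * read_length / 1000
  tibble(n_hits = n_hits, gene_length = gene_length, read_length = read_length,
         hits_per_kb = hpk, coverage = cov,
         hits_per_kb_rounded = round(hpk, 2), coverage_rounded = round(cov, 2))
}

#' Per-gene coverage profile of a gene set
#'
#' Convenience pipeline: unique hits per gene, then the hits/kb and coverage
#' formulas.
#'
#' @inheritParams count_unique_hits
#' @param read_length Read length used in the coverage formula; defaults to
#'   the median read length of `reads`.
#' @return Tibble: `gene_id`, `gene_length`, `n_unique_hits`, `hits_per_kb`,
#'   `coverage`.
#' @export
gene_coverage <- function(reads, genes, read_length = NULL, seed_len = 7L,
                          min_identity = 0.80, seed_stride = 1L) {
  if (is.null(read_length)) read_length <- median(nchar(reads$seq))
  hits <- count_unique_hits(reads, genes, seed_len, min_identity, seed_stride)
  cv <- coverage_from_hits(hits$n_unique_hits, hits$gene_length, read_length)
  hits$hits_per_kb <- cv$hits_per_kb
  hits$coverage <- cv$coverage
  attr(hits, "read_length") <- read_length
  hits
}

#' Bootstrap percentile confidence interval for a median
#'
#' Resamples `length(values)` observations with replacement `iterations`
#' times, takes the median of each replicate, and reports the percentile
#' bounds at `(1 - level)/2` and `1 - (1 - level)/2`.
#'
#' @param values Numeric vector (length at least 2).
#' @param iterations Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_median_ci <- function(values, iterations = 1000L, level = 0.95, seed = 1L) {
  if (length(values) < 2) abort("need at least 2 values for a bootstrap CI")
  values <- sort(values)  # canonical internal ordering: order-invariant given seed
  n <- length(values)
  meds <- withr::with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      median(values[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- quantile(meds, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = ci[1], upper = ci[2])
}

#' Flag box-plot outliers above the upper whisker
#'
#' The threshold is `Q3 + 1.5 * (Q3 - Q1)` with quartiles computed by linear
#' interpolation between order statistics (quantile type 7); values strictly
#' above the threshold are flagged.
#'
#' @param values Numeric vector (length at least 4).
#' @return A list with `threshold` and `flags` (logical vector).
#' @export
flag_outliers <- function(values) {
  if (length(values) < 4) abort("need at least 4 values to define quartiles")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  threshold <- q[2] + 1.5 * (q[2] - q[1])
  list(threshold = threshold, flags = values > threshold)
}

#' Summarise a gene coverage profile
#'
#' Medians with bootstrap confidence intervals for hits/kb and coverage over
#' the genes with at least one hit (zero-hit genes are excluded from the
#' medians and reported separately), plus the box-plot outlier census.
#'
#' @param records Tibble from [gene_coverage()] (or with the same columns).
#' @param iterations Bootstrap iterations.
#' @param level Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `gene_coverage_summary`.
#' @export
summarize_gene_coverage <- function(records, iterations = 1000L, level = 0.95, seed = 1L) {
  with_hits <- records[records$n_unique_hits > 0, , drop = FALSE]
  if (nrow(with_hits) < 4) abort("need at least 4 genes with hits to summarise")
  ci_h <- bootstrap_median_ci(with_hits$hits_per_kb, iterations, level, seed)
  ci_c <- bootstrap_median_ci(with_hits$coverage, iterations, level, seed)
  out <- flag_outliers(with_hits$coverage)
  structure(list(
    n_genes = nrow(records),
    n_genes_with_hits = nrow(with_hits),
    n_zero_hit = nrow(records) - nrow(with_hits),
    median_hits_per_kb = median(with_hits$hits_per_kb),
    hits_per_kb_ci = ci_h,
    median_coverage = median(with_hits$coverage),
    coverage_ci = ci_c,
    outlier_threshold = out$threshold,
    n_outliers = sum(out$flags),
    iterations = iterations, level = level, seed = seed,
    records = with_hits %>% mutate(outlier = out$flags)
  ), class = "gene_coverage_summary")
}

#' @export
print.gene_coverage_summary <- function(x, ...) {
  cat(sprintf("Gene coverage summary: %d genes, %d with >=1 unique hit (%d zero-hit)\n",
              x$n_genes, x$n_genes_with_hits, x$n_zero_hit))
  cat(sprintf("  median hits/kb: %.2f (%d%% CI %.2f - %.2f)\n",
              x$median_hits_per_kb, round(100 * x$level),
              x$hits_per_kb_ci[["lower"]], x$hits_per_kb_ci[["upper"]]))
  cat(sprintf("  median coverage: %.2fx (%d%% CI %.2fx - %.2fx)\n",
              x$median_coverage, round(100 * x$level),
              x$coverage_ci[["lower"]], x$coverage_ci[["upper"]]))
  cat(sprintf("  %d outlier gene(s) above %.3fx (Q3 + 1.5 IQR)\n",
              x$n_outliers, x$outlier_threshold))
  invisible(x)
}

#' @method tidy gene_coverage_summary
#' @export
tidy.gene_coverage_summary <- function(x, ...) {
  x$records
}

#' @method glance gene_coverage_summary
#' @export
glance.gene_coverage_summary <- function(x, ...) {
  tibble(n_genes = x$n_genes, n_genes_with_hits = x$n_genes_with_hits,
         n_zero_hit = x$n_zero_hit,
         median_hits_per_kb = x$median_hits_per_kb,
         hits_per_kb_ci_lower = x$hits_per_kb_ci[["lower"]],
         hits_per_kb_ci_upper = x$hits_per_kb_ci[["upper"]],
         median_coverage = x$median_coverage,
         coverage_ci_lower = x$coverage_ci[["lower"]],
         coverage_ci_upper = x$coverage_ci[["upper"]],
         outlier_threshold = x$outlier_threshold, n_outliers = x$n_outliers,
         iterations = x$iterations, seed = x$seed)
}
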