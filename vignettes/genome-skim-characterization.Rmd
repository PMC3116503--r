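---
title: "Characterizing a genome from a low-coverage skim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a genome from a low-coverage skim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimtools)
```

## The problem

A genome skim is a shotgun sequencing run that covers the nuclear genome far
below 1× — too shallow to assemble low-copy sequence, but deep enough to
saturate everything present in many copies per cell: the chloroplast genome
(hundreds of copies), the mitochondrial genome, the tandem ribosomal DNA
arrays (hundreds to thousands of copies), and abundant dispersed repeats. At
~0.5× overall coverage with 40 nt reads, those high-copy components reach
tens to hundreds of fold depth and can be characterized essentially
completely, while the single-copy gene space can still be surveyed
statistically through per-gene hit counts.

skimtools implements that analysis chain as composable functions over
tibbles: read cleaning, reference-guided consensus with masking,
quantification of intragenomic polymorphism among rDNA repeat copies with
control-lane error calibration, compartment classification and coverage /
copy-number arithmetic, gene-space coverage with bootstrap confidence
intervals, and SSR / dispersed-repeat detection. A synthetic skim simulator
generates multi-compartment genomes and read pools with complete ground
truth, so every stage is testable without external data.

## Read cleaning

Three rules, applied in a fixed order:

1. **N removal** — any read containing an `N` is removed.
2. **Adapter removal** — a read is removed when any ungapped overlap of at
   least 10 nt with the adapter (either orientation) reaches 90% identity.
   The overlap and identity thresholds are explicit parameters because the
   rule is otherwise underdetermined; the defaults make it deterministic and
   conservative.
3. **Tail trimming** — each read is truncated at the first base with quality
   ≤ Q2 and everything after it. Q2 is the "unscorable" value that
   early-Illumina pipelines encoded as the letter "B"; expressing the rule
   as a quality threshold makes it encoding-agnostic (offsets 33 and 64 are
   both supported by `read_fastq()`). Reads trimmed to nothing are counted
   separately as "emptied".

Both pools are kept: `qc_reads()` returns the cleaned (untrimmed) pool,
which de novo assembly prefers, and the cleaned-and-trimmed pool.

## Read placement and consensus

`place_reads()` is a gapless seed-and-extend matcher (Rcpp core): exact
k-mers of the read (every offset by default) are looked up in a hashed
reference index, each candidate diagonal is scored over the full read, and
placements at or above the identity threshold are reported, best first, ties
broken by lower reference position then `+` strand. Defaults are k = 11 with
85% identity for consensus work, and k = 7 with 80% identity for
divergent-gene matching. Gapless extension is a deliberate restriction: at
40 nt, reads spanning indels simply fail the identity threshold, and
indel-rich regions are left to masking rather than mis-reconstructed.

Sensitivity is exact for near-perfect reads: a placement whose longest clean
stretch is ≥ k is always found. For k = 11 and 40 nt reads this is
guaranteed up to 2 mismatches; beyond that, sensitivity decays gracefully.
The oracle-agreement tests therefore plant ≤ 2 errors per read; the
simulation-based tests run at the 0.4% default error rate, where the loss is
negligible.

Circular references (plastome; tandem rDNA units, which wrap at the unit
junction exactly like a circle; the phage-like control) are handled by a
virtual extension of the first read-length − 1 bases, with positions
reported modulo length.

`build_pileup()` tallies each aligned read base into one column; `N` read
bases count toward total depth but are excluded from every evidence
denominator. `call_consensus()` takes the majority base over non-N counts
and masks to `N` when effective depth < 3, majority proportion < 0.7, or —
with SNP masking on — when the second base reaches 20% (maskable as `N` or
an IUPAC two-base code). Ties are broken alphabetically and flagged.
Contigs are maximal runs of covered positions; `assembly_stats()` reports
their count, N50 (descending cumulative-sum definition), longest length and
the median depth over covered positions.

Two consequences worth knowing:

* each read contributes its single best placement to a pileup, so exact
  duplicated regions (the two plastome IR arms) accumulate all their reads
  on the first copy — the same reason reference-guided pipelines assemble
  plastomes against a single-IR reference;
* at skim-style uniform starts the outermost read-length of a linear
  reference sits at reduced depth, so "consensus equals template" holds for
  the interior; tests exclude the first and last 40 bases.

## rDNA intragenomic polymorphism

Repeat arrays are sequenced as a population of copies, so a pileup against
the unit consensus measures variation *among copies*. The procedure:

1. discard reads with mean Phred < 20; convert remaining bases with Phred
   < 20 to `N` (length preserved), so weak evidence leaves both numerator
   and denominator;
2. place the filtered reads on the unit consensus and tally, per position,
   the proportion of non-N bases differing from the consensus
   (`discordance_profile()`);
3. call positions with ≥ 2% differing reads polymorphic
   (`call_polymorphic()`), and report `100 × calls / region length` to one
   decimal, optionally per annotated region supplied as a BED-style table;
4. calibrate the threshold by running the same profile on the spiked
   sequencing control (`control_error_profile()`): mean discordance, the
   maximum position, and counts above any cutoffs of interest. The 2%
   threshold is deliberately conservative relative to typical post-filter
   control error (< 0.05% mean, < 0.7% per position); systematic-error
   positions in the control are reported, never auto-removed.

Positions with no effective coverage are reported missing (`NA`), not zero.
The percentage denominator is the full region length, matching how such
figures are quoted.

## Compartments, coverage, copy number

`classify_reads()` assigns each read to the first compartment in a fixed
priority order — chloroplast, mitochondrial, rDNA, control, then any extra
labels — that yields a qualifying placement (k = 11, 90% identity by
default). The priority makes classification deterministic when compartments
share sequence (organellar transfers). Everything unmatched is "nuclear".

The arithmetic helpers mirror how skim studies report results:

* overall coverage = yield / genome size; nuclear coverage = yield × (1 −
  Σ high-copy fractions) / genome size, both rounded to one decimal;
* repeat copy number = median depth of the repeat consensus / nuclear
  coverage (`estimate_copy_number()`), rounded to an integer;
* flow-cytometry conversion: 1C Mbp = (2C pg / 2) × 978, rounded to the
  nearest 5 Mbp (`pg_to_mbp()`).

## Gene-space coverage

For a reference gene set (soft-masked regions excluded from seeding),
`count_unique_hits()` counts each read at most once per gene; a read may hit
several genes. Coverage per gene is `(hits/kb × read length)/1000`
(`coverage_from_hits()`). `summarize_gene_coverage()` reports medians over
genes with ≥ 1 hit (zero-hit genes counted separately), 95% percentile
bootstrap confidence intervals for both medians (1,000 iterations, seeded,
order-invariant), and the box-plot outlier census with threshold Q3 + 1.5 ×
IQR, quartiles by linear interpolation (quantile type 7 — the convention is
recorded because it is not universal). Coverage is overestimated when reads
overlap (e.g. PCR duplicates); this is a property, not a bug, and is tested
as such.

## SSRs and repeats

`scan_ssrs()` reports all maximal perfect tandem repeats of 2–6 nt motifs —
di/tri ≥ 4 units, tetra/penta/hexa ≥ 3 — in contigs of at least 150 bp (the
flank needed for primer design). Runs are attributed to their shortest
period: motifs that are repetitions of a shorter unit (including
homopolymers) are never reported. The reported motif preserves observed
strand and phase; the canonical form (least rotation) is bookkeeping only.
The scanner's normative definition is the regex enumeration it is tested
against. `ssr_primer_feasibility()` asks only whether an amplicon window of
100–450 bp containing the locus with ≥ 18 nt flanks fits in the contig; no
primer chemistry is attempted.

`find_repeats()` finds gapless local self-matches (direct, and inverted via
the reverse complement) longer than 30 bp at ≥ 85% identity, seeded by
shared exact 12-mers and extended by X-drop scoring (match +1, mismatch
−id/(1−id), so a segment scores ≥ 0 exactly when it meets the identity
threshold). "Greater than 30 bp" is read strictly; `inclusive = TRUE`
switches to ≥. `detect_quadripartite()` takes the longest inverted
self-match at ≥ 99% identity and ≥ 1 kb as the IR pair and labels the two
remaining arcs LSC (longer) and SSC (shorter); the identity and length
floors are configurable because quadripartite conventions vary. Absence of
an IR is a result, not an error.

`classify_vs_repeat_library()` counts each query once however many library
elements it hits (70% identity default) and tabulates per-family counts
from library labels. `pairwise_identity()` removes columns gapped in either
aligned sequence before computing matches over the remainder.

## The simulator: what it emulates, and what it does not

`genome_spec()` describes a genome whose skim has the statistical structure
the analyses assume; `build_mock_genome()` instantiates it deterministically
from the seed, and `simulate_reads()` draws the pool.

Defaults are the study conditions the package is organized around:
chloroplast / mitochondrial / rDNA read fractions of 11.8%, 3.4% and 1.8%
(the nuclear background length is solved so these hold exactly in
expectation); 40 nt reads; an 18S-5.8S-26S-like cistron unit of 7,541 bp
with a polymorphic-site rate of 19/7541 (~0.3% of sites); a 120 bp 5S-like
unit with 26.7% of sites polymorphic; minor-copy fractions drawn from
2–17%; a 5,386 bp circular control; constant 0.4% substitution error at Q24
(the published control error of < 0.05% is a post-filter figure, so the raw
rate is deliberately higher). Array copy numbers default to desk scale (10
and 40) rather than the ~1,845 and ~1,015 of a real rDNA complement; tests
that need fine minor-allele resolution raise them to 100. Polymorphic sites
may be drawn binomially (`poly_site_rate`) or fixed exactly
(`n_poly_sites`); minor alleles are placed by shuffling copies once and
giving the first `round(f × n)` the minor base, so the realized fraction is
recorded exactly.

The simulator intentionally omits: paired ends, indel errors, PCR
duplicates, GC bias, quality decay along the read (beyond an optional
unscorable tail), chimeras, and heterozygosity in single-copy sequence.
Passing tests therefore demonstrate the *computational* correctness of each
stage under a clean substitution-error model — not robustness to every
artifact of real libraries. The three artifact knobs it does have (N
injection, adapter prefixes, Q2 tails) exist to exercise the cleaning rules
against known truth.

## Numerical and design choices

* Coordinates: every user-facing table is 1-based inclusive, R's native
  convention (SAM positions ingest unshifted). One convention everywhere
  beats a fast internal one that leaks.
* Majority/discordance denominators exclude `N` evidence; total depth
  (including `N`) is retained for depth accounting and contig splitting.
* Majority ties: alphabetical, flagged in the output.
* Bootstrap: values are sorted internally before seeding, so the interval is
  invariant to input order given the seed.
* Quartiles/percentiles: type 7 throughout.
* Degenerate inputs error early and descriptively: empty FASTA, wrong Phred
  offset (negative decoded quality), missing qualities where a rule needs
  them, placements overrunning a linear reference, zero genome size,
  fewer than 2 (CI) or 4 (quartile) values.
* Problem sizes in the test suite are chosen for desk-scale determinism:
  references of 0.5–8 kb, pools of 10^3–10^5 reads, depths of 100–700×,
  20-seed calibration loops, 500-repetition bootstrap studies. These mirror
  the regimes the statistics operate in (depth, not genome size, drives
  them) while keeping the full suite under a few minutes.

## Known limitations

* Gapless placement cannot represent indel variation; divergent regions are
  masked, not resolved.
* Single-best placement under-covers exact duplicates (IR arms) — by
  design, but it means `detect_quadripartite()` should run on the assembled
  sequence, not the pileup.
* The discordance model cannot separate within-array from between-array
  variation, and does not phase variants into copy haplotypes.
* `classify_vs_repeat_library()` at 70% identity over 40 nt reads is a
  census, not an annotation; repeat taxonomy is out of scope.
* Primer feasibility is geometric only.
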