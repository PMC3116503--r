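Package: skimtools
Title: Characterization of the High-Copy Genome Fraction from Low-Coverage Genome Skims
Version: 0.1.0
Authors@R:
    person("A.", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing a genome from very low-coverage ("genome
    skim") short-read shotgun data. Implements reference-guided read placement,
    pileup construction and consensus calling with proportion/depth/SNP masking,
    quantification of intragenomic polymorphism among ribosomal DNA repeat
    copies with control-lane error calibration, classification of reads into
    organellar and ribosomal compartments, genome coverage and repeat
    copy-number estimation, gene-space coverage profiling with bootstrap
    confidence intervals, microsatellite (SSR) and dispersed-repeat detection,
    and a synthetic multi-compartment skim simulator that emits ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
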