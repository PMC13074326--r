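Package: indelfp
Title: InDel Marker Development, Diversity Analysis and DNA Fingerprinting
    for Germplasm Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for developing insertion/deletion (InDel) molecular
    markers from genome-wide variant catalogues and applying them to
    germplasm characterisation. Covers variant cataloguing and
    per-chromosome summaries, stepwise marker screening (quality, length,
    repeat exclusion, flank single-copy check, spacing, genic balance),
    PCR primer design under thermodynamic constraints, polymorphism
    information content (PIC) statistics from gel band codes, genetic
    distances with UPGMA/neighbor-joining trees and PCA, simplified
    maximum-likelihood admixture with K selection by cross-validation
    error and the Evanno delta-K statistic, and construction of digit-string
    DNA fingerprints from a core biallelic marker panel. Includes seeded
    simulators for reference genomes, implanted InDels and structured
    populations with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
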