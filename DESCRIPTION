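Package: mapanchor
Title: Linkage-Map Validation of Genome Assemblies and Recombination-Rate
    Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating chromosome-level genome assemblies with
    dense genetic linkage maps and for analysing variation in recombination
    rate. Builds a multi-family compendium of mapped SNPs, assigns consensus
    linkage groups to contigs, detects chimeric blocks of mis-assigned SNPs,
    classifies SNPs with a high-confidence decision tree, orders and orients
    contigs into pseudomolecules from multi-map linkage evidence, and
    classifies concordance against a reference layout. Recombination-rate
    tools include chromosome-level rates from distal markers, Marey-map
    local-regression rate profiles, hotspot and coldspot quadrat tests of
    complete spatial randomness, and variance partitioning across families,
    sexes, and chromosomes. A meiosis and genotyping simulator with known
    truth makes every stage testable by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
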