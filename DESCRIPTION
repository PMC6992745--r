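Package: radpopgen
Title: Population Structure and Diagnostic SNP Markers from RAD-Seq Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of reduced-representation (RAD-Seq) SNP genotype data for
    hierarchically structured populations: Stacks-style locus presence
    filtering, genotype principal component analysis and identity-by-state
    multidimensional scaling, pairwise Weir-Cockerham fixation indices at the
    group and accession level with rank-sum comparisons, supervised
    ancestry-fraction estimation by expectation-maximisation to flag admixed
    and transplanted accessions, and discovery of fixed-difference diagnostic
    SNP markers for two- and three-group partitions with genomic-region and
    amino-acid-effect classification. Includes a Balding-Nichols simulator
    that generates annotated toy datasets with known truth for every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    vcfR,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
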