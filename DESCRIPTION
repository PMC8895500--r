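Package: imprintr
Title: Allele-Specific Expression and Imprinting-Control-Region Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for genomic-imprinting studies in hybrid mouse
    crosses. Computes the P-score allelic-expression statistic from
    maternal/paternal read counts, tests for allelic-expression switches
    across genotypes with Kruskal-Wallis and exact binomial tests, quantifies
    imprinted-gene expression in TPM with fold-change and ANOVA/Fisher-LSD
    group comparisons, quantifies imprinting-control-region DNA methylation
    (total and allele-split) from read-level bisulfite CpG calls, and performs
    clone-level analysis of bacterial-colony bisulfite sequencing with
    unconverted-cytosine fingerprint deduplication. A seeded synthetic-data
    generator emulates a 129xDBA maternal-zygotic mutant cross so every stage
    is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
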