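Package: netmsea
Title: Marker-Set Enrichment and Network Key-Driver Analysis for GWAS Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for integrating genome-wide
    association summary statistics with tissue-specific eQTL maps, gene-set
    catalogs and gene networks. Implements linkage-disequilibrium pruning of
    markers, marker-set enrichment analysis (MSEA) with a multi-quantile
    chi-square-like statistic and permutation null, cross-cohort meta-analysis,
    redundancy merging of significant gene sets into supersets, key-driver
    analysis on regulatory and protein-protein interaction networks,
    signature-based drug repositioning filters, and a paired pre/post
    biomarker screen for electronic medical records. A synthetic-data module
    generates every pipeline input with planted ground truth so the full chain
    is testable without external data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
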