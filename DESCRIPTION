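Package: coabnet
Title: Condition-Specific Co-Abundance Networks and Network-Proximity Drug
    Target Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds condition-specific protein co-abundance networks from
    time-course proteomics (correlation, permutation empirical p-values,
    Benjamini-Hochberg FDR, density-guided thresholding), superimposes them
    on a literature protein-protein interaction network, and prioritizes
    drug-target candidates by weighted network proximity to seed targets.
    Includes four prioritization schemes (shortest-path proximity, kernel
    distance, random walk with restart and its degree-aware variant),
    cross-validated AUROC evaluation against degree-preserving random-edge
    nulls, combined ranking with abundance and expression evidence,
    candidate-to-target distance statistics with degree-matched node nulls,
    gene-set enrichment, Jaccard pathway networks, and a synthetic-data
    generator with planted co-abundance modules for end-to-end testing.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
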