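Package: cavemapr
Title: GBS-Based F2 Linkage Mapping, Binary-Trait QTL Scans, and
    Cross-Species Synteny Anchoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds de-novo genetic linkage maps from genotyping-by-sequencing
    (GBS) marker data for F2 intercrosses between divergent morphotypes, as in
    cave-vs-surface fish crosses. Covers the full desk analysis: IUPAC-coded
    marker screening (parental consensus, F1 confirmation, segregation-
    distortion chi-square filtering), two-point recombination-fraction
    estimation by EM, independence-LOD grouping, regression-style marker
    ordering with Kosambi distances, single-QTL scans of binary traits
    (marker regression, Haley-Knott, EM interval mapping) with permutation
    thresholds, BLAST-hit resolution for cross-species synteny assignment,
    and anchoring of unplaced genome scaffolds to linkage groups. A seeded
    synthetic-data generator reproduces the statistical structure of a GBS
    cross so every stage is testable without sequencing data.
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
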