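Package: dcmap
Title: Cross-Species Transcriptome Mapping of Dendritic Cell Subsets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns human and mouse mononuclear phagocyte subsets by their
    expression profiles. Derives tissue-corrected, rank-based gene signatures
    for sorted cell subsets (signal-to-noise ranking after removal of genes
    differentially expressed between anatomical sources), scores them against
    reference profiles with a directional Kolmogorov-Smirnov connectivity
    statistic in the style of the Connectivity Map, assigns significance by
    gene-membership permutation, translates signatures across species through
    ortholog tables, and clusters subset profiles hierarchically. Includes a
    synthetic two-species microarray cohort generator with planted lineage
    homology so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    ape,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
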