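Package: spotcoloc
Title: Spatial Colocalization and Composition Analysis for Visium Spot Data
Version: 0.1.0
Authors@R:
    person("spotcoloc", "developers", email = "spotcoloc@example.org",
           role = c("aut", "cre"))
Description: Tools for spot-level analysis of Visium spatial transcriptomics
    data: reading SpaceRanger-style feature-barcode matrices and tissue
    position tables, spot quality-control filtering, median-library-size
    normalization, Delaunay spot-adjacency graphs, a permutation-based
    gene-pair colocalization statistic with empirical p-values,
    deconvolution-proportion composition summaries (dominant and enriched
    spots, per-condition subset frequencies), Wilcoxon rank-sum marker
    testing with log2 fold-change filtering, and a synthetic Visium-like
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    deldir,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
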