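Package: markgate
Title: Signature-Driven Cell-Type Annotation for Spatial Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised cell-type annotation for single-cell-resolved
    spatial proteomics and transcriptomics. Cells are scored against
    expert-defined marker signatures, per-type positivity thresholds are
    learned by micro-clustering followed by rank-ordered segmented
    regression with AIC breakpoint selection and a misclassification-
    minimizing grid search, and multi-label cells are resolved by
    k-nearest-neighbour voting inside the relevant marker subspace.
    Includes benchmarking metrics against reference labelings, marker
    enrichment statistics, Delaunay-based cell-cell interaction analysis,
    and a seeded synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    RANN,
    igraph,
    deldir,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
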