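Package: k9me
Title: Tissue-Specific Gene Derepression Analysis After H3K9 Methylation Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for linking loss of H3K9 di-/tri-methylation to
    tissue-specific gene derepression in C. elegans-style genomes: library-size
    count normalization with a pseudo-count-8 log2 transform, an exact
    conditional-binomial differential count test with Benjamini-Hochberg
    correction, ChIC-seq window quantification against an MNase control with
    consecutive-window heterochromatin domain calling, position-weight-matrix
    genome scanning with promoter motif-enrichment statistics, ATAC-seq Tn5
    cut-site shifting with peak feature annotation and expression-accessibility
    gene grouping (Groups A/B/C), DamID nuclear-periphery bin enrichment, and 3D
    two-channel image analysis (seeded watershed nucleus segmentation,
    Laplacian-of-Gaussian focus detection, anisotropic Euclidean
    distance-to-periphery measurement). Includes a fully deterministic synthetic
    data generator that plants known truth for every stage, so the complete
    pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
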