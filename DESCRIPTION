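Package: fragseq
Title: Spatial Niche Reconstruction from Fragment-Based Single-Cell Hashing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational workflow for fragment-based single-cell
    transcriptomics, in which partially dissociated tissue fragments
    (200-450 um cellular communities) are sorted into wells, hashed with
    fragment-specific DNA barcodes and pooled for single-cell RNA
    sequencing. Provides hashing-barcode design under a minimum Hamming
    distance constraint, classification of cells to fragments from
    barcode UMI counts, time-of-flight to fragment-size calibration from
    standard beads, reconstruction of each fragment's spatial niche
    (liver lobule layer via landmark-gene zonation coordinates, or
    metastasis proximity via landmark cell types), niche-resolved
    pseudobulk differential expression with ordered-factor covariates,
    cell-type abundance testing, permutation-based ligand-receptor
    interaction scoring, post-segmentation operators and a colocalization
    permutation test for imaging-based validation data, and a synthetic
    data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    edgeR,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
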