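Package: ctcfusion
Title: Copy-Number and Proteomic Evidence Against Tumor-Leukocyte Fusion
    in Circulating Tumor Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for deciding whether CD45+/cytokeratin+ circulating cells
    carry a bona fide tumor genome or a tumor-leukocyte fusion genome.
    Simulates single-cell bin-level read counts with known copy-number truth,
    performs GC-bias correction, genome-mean ratio normalization and circular
    binary segmentation, constructs synthetic fusion profiles by summing
    parental bin counts, quantifies the expected compression of copy-number
    alteration amplitudes under fusion with a diploid genome, scores clonality
    across single cells, classifies rare cells from immunofluorescence
    intensity features (slide-wide cytokeratin threshold plus a CD45 logistic
    classifier with repeated cross-validation), and gates imaging mass
    cytometry ion-count tables (mask QC filters, percentile normalization,
    arcsinh transform, hierarchical gating, kNN-Jaccard-Louvain clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
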