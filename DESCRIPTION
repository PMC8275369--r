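Package: encore
Title: Enhancer Window Classification and Boundary Condensation from
    Epigenetic Signal Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects enhancers in 4 kb genomic windows from five co-registered
    epigenetic signal tracks (chromatin accessibility plus four histone
    marks) with a small convolutional neural network trained on
    STARR-seq-derived labels, then condenses each positive window to
    core-enhancer boundaries at 10 bp resolution using gradient-weighted
    class activation mapping (Grad-CAM).  Includes training-set construction
    from peak files, genome-wide sliding-window scanning, annotation
    refinement, a synthetic five-assay track generator with ground-truth
    enhancer boundaries, and evaluation utilities (auROC/auPRC, grouped
    cross-validation, boundary-recovery metrics).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
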