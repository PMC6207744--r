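Package: enhancerpred
Title: Enhancer Prediction from ATAC-seq Open Chromatin Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts enhancers among ATAC-seq open chromatin regions (OCRs)
    using multilayer-perceptron classifiers trained on 24 accessibility,
    sequence, motif and genomic-location features extracted per peak.
    Provides strict readers for narrowPeak, fragment BED/BAM, ChromHMM-style
    segmentations, JASPAR/HOMER motif libraries and genotype tables;
    ChromHMM-state labeling with emission-based state harmonization;
    within-cell-type, cross-cell-type and pooled ("combined") model training
    with leakage-free stratified cross-validation; single-feature and
    backward-elimination feature ranking; individual-level cohort analysis
    including consensus peaks, leave-one-individual-out evaluation and
    chromatin-accessibility-QTL genotype/probability correlation; and a fully
    self-contained synthetic ATAC-seq data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    e1071,
    randomForest,
    MASS,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    nnet,
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
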