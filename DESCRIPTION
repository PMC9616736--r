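Package: thirstState
Title: Thirst-State Brain Analysis: Single-Cell QC, Zero-Inflation-Aware
    Differential Expression, Calcium Response Classification, and
    Astrocyte-Synapse Vicinity Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-stage analysis toolkit for studying internal-state
    (thirst) signatures in the Drosophila brain. Implements barcode-level
    quality-control filtering and marker co-expression doublet detection
    for single-cell RNA-seq, bimodal expression thresholding, cluster-tree
    fusion by differential-expression gene counts, per-gene zero-inflated
    negative binomial fitting with observational weights and a weighted
    negative binomial likelihood-ratio test, fluorescence trace dF/F0
    response classification with contingency statistics, astrocyte
    skeleton to synapse vicinity profiling with bootstrap resampling
    tests, and behavioral preference/consumption indices. A synthetic
    data module generates count matrices, traces, and anatomy with
    planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pracma,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, RNASeq, DifferentialExpression, QualityControl,
    Software
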