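Package: ProxiStress
Title: Ratiometric Proximity Proteomics and Mechanical-Stress Shift Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of TurboID/miniTurbo proximity-labeling proteomics for a
    chaperone bait profiled against dual controls. Implements Perseus-style
    label-free quantification preprocessing (decoy filtering, log2 transform,
    median normalization, valid-value filtering, downshifted-normal
    imputation), three-control ratiometric enrichment of bait-proximal
    proteins, combined-experiment detection overlap and PCA quality control,
    a fold-change gate for muscle-expressed proteins followed by a
    stress-shift volcano analysis, transcript/protein concordance quadrant
    integration with per-quadrant over-representation analysis, and a
    self-contained statistical kernel (two-sample t-test,
    Benjamini-Hochberg adjustment, hypergeometric tail, preranked GSEA,
    PCA). A synthetic-data generator with planted ground truth makes every
    stage verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
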