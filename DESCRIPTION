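Package: matreg
Title: Consensus Inference of Tumor Matrisome Regulatory Modules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for charting tumor-type-specific
    extracellular-matrix (matrisome) gene signatures and the transcriptional
    architecture above them. Provides a synthetic multi-tumor cohort
    generator with planted ground truth; global expression landscape tools
    (per-tumor gene ranking, inter-tumor correlation clustering,
    multi-classifier recall with contingency testing); signature inference
    versus matched healthy tissue and the rest of the cohort; a multi-step
    consensus engine for transcription-factor to matrisome-target modules
    (prior mining, Fisher-z correlation separation with a Youden-index
    threshold, adaptive-lasso pruning, BIC-scored Gaussian network search and
    lasso neighborhood selection with fold stability, two-of-three
    consensus); master-regulator identification from driver mutation
    frequencies and protein-protein interaction coverage with pathway
    over-representation; and prognostic/druggability assessment of module
    activity via mean-dichotomized Kaplan-Meier survival and on/off-label
    drug mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    survival,
    e1071,
    nnet,
    rpart,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
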