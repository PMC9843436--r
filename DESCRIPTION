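Package: histomil
Title: Desk-Scale Histology Image Analysis with Multiple-Instance Learning and Survival Risk Grouping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for slide-level analysis of H&E
    histology images at desk scale: synthetic-slide and tissue-microarray
    generation with planted texture classes and survival labels, Otsu
    foreground detection and patch tiling with tissue/tumor-fraction
    filters, class balancing with geometric augmentation recipes, pixel
    texture segmentation trained with weighted cross-entropy plus
    Lovasz-Softmax, patch classifiers trained with two multiple-instance
    learning loss variants, slide-level positive-ratio mutation calling,
    tissue-microarray core and patient consensus rules, a Cox
    partial-likelihood survival head with hazard ensembling and a
    constrained two-cutoff risk-group search, and the evaluation
    statistics (IoU, F1, MCC, ROC AUC, exact binomial intervals) used to
    report such analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    survival,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
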