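Package: dtiscope
Title: Drug-Target Interaction Prediction from Perturbation Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A transcriptome-based pipeline for predicting drug-target
    interactions (DTIs) from L1000-style landmark-gene perturbation profiles.
    Replicate trials of each drug or gene-knockdown entity are aggregated into
    a credible set of one or two representative profiles via correlation-guided
    k-means; drug and gene profiles are fused serially into classification
    samples; a small feed-forward network is trained with a penalized
    cross-entropy objective that rewards confident negative-class probability
    on true negatives; and unlabeled drug-gene pairs are ranked by the logit
    distance to the decision boundary (D-score). A synthetic-panel generator
    with planted drug-target structure makes the whole pipeline testable
    offline, and sliding-bin overlap curves evaluate ranked predictions
    against reference interaction sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
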