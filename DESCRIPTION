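Package: mricoder
Title: Billing-Code Prediction for MRI Exams from Scanner Log Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-exam medical procedure billing codes (Tarmed-style,
    count-valued) from MRI modality log events. Assembles raw scanner events
    into exam instances, standardizes user-defined MR sequence names
    heuristically from acquisition parameters, extracts workflow features
    (acquisition and idle time, table movement, contrast, coils), and trains
    multi-output classifiers (binary relevance, classifier chains, and
    ensembles of classifier chains over MLP, RBF-SVM, or random-forest base
    learners). Ships multi-label evaluation metrics (micro/macro
    precision/recall/F1, subset accuracy, label cardinality/density/diversity),
    coding-economics analyses (under-/overcoding reimbursement deltas), and a
    seeded synthetic exam-log generator with a technologist coding-error
    simulator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    rlang,
    stringr,
    jsonlite,
    readr,
    stats,
    utils,
    tools,
    nnet,
    e1071,
    randomForest,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
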