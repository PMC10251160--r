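Package: fnacost
Title: Cost and Diagnostic Accuracy of Fine-Needle Cytology Triage of
    Lymphadenopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort replay model for the diagnostic work-up of
    clinically suspicious lymphadenopathy.  Pathways of individual
    lymphadenopathies (first fine-needle aspiration cytology, optional
    repeat cytology or surgical biopsy over up to three cycles) are
    replayed through a four-state transition model (benign, ALUS,
    suspicious, malignant) to tally state occupancy, accumulate
    reimbursement costs under an FNAC-first strategy versus upfront
    surgical biopsy, and derive diagnostic accuracy under a composite or
    histology-only reference standard.  Includes a built-in 535-node
    reference cohort, a seeded synthetic-cohort generator with parameter
    recovery, one-way cost sensitivity analysis, and broom-style tidiers
    with ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
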