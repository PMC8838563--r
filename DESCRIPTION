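Package: gynsurgnlp
Title: Rule-Based Extraction of Gynecologic Surgical History from Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A rule-based clinical natural language processing pipeline that
    determines a patient's gynecologic surgical history status (one of six
    mutually exclusive categories covering hysterectomy and unilateral or
    bilateral oophorectomy) from longitudinal free-text clinical notes.
    Includes section segmentation and relevance filtering, sentence detection,
    tokenization, dictionary-based concept matching with exclusion handling,
    NegEx-style assertion classification, laterality resolution, in-sentence
    date extraction, patient-level status aggregation, a full evaluation suite
    (per-class/macro/weighted precision-recall-F1, accuracy, percent agreement,
    Cohen's kappa, reverse-chronological recovery-ratio curves, and a
    discrepancy taxonomy), and a seeded synthetic EHR corpus generator that
    emulates the information gaps characteristic of single-institution records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
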