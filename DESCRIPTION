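Package: adrminer
Title: Rule-Based Detection of Adverse Drug Reactions in Free-Text Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase text-mining pipeline that flags possible adverse drug
    reactions (ADRs) in free-text electronic health record notes. Phase I flags
    candidate text blocks with configurable trigger strategies and finds
    ADR-term and drug-name mentions with a MedDRA-style dictionary, pairing
    them by character proximity. Phase II refines candidates through
    toggleable stages (drug and term list filters, deduplication, one-edit
    variant matching, negation windowing, seriousness classification) and
    emits unique drug-event alerts. Includes an evaluation harness
    (sensitivity, positive predictive value, F-measure, serious-ADR stratum)
    and a seeded synthetic-corpus generator so every stage is testable
    without licensed terminologies.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
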