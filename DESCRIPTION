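Package: adrmine
Title: Signal Mining for Adverse Drug Reactions in Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects adverse-drug-reaction (ADR) signals in spontaneous
    reporting data. Implements contingency-cube counting over de-normalized
    report warehouses, the standard disproportionality measures (proportional
    reporting ratio, reporting odds ratio, information component, Yates
    chi-squared, leverage) with the MHRA composite criterion, a cube-based
    miner for single-drug to symptom signals stratified by demographic
    attributes, and an associative-classification miner (CR-tree with
    FP-growth style pattern growth) for multidrug to symptom interaction
    signals. Ships a seeded synthetic report generator with injectable
    drug-ADR associations for end-to-end validation, and a command-line
    interface for reproducible runs.
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
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
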