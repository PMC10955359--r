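Package: coopdetect
Title: Simulation and Signal-Detection Analysis of Cooperation Prediction in
    Repeated Prisoner's Dilemmas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative models and measurement tools for studies in which
    raters predict the choices of players in a 'Split or Take All' repeated
    Prisoner's Dilemma with a random-stopping rule. Simulates cohorts of
    conditional-cooperator and non-cooperator players, matched-pair game
    histories, and raters who form first and second impressions under four
    information treatments (no information, gender label, photo, video) from
    correlated gender-specific beliefs, appearance cues and behavioural
    history. Implements the signal-detection measurement layer (cooperator
    and cheater detection rates, rate clamping, z-score accuracy and bias,
    correctness, odds ratio, belief-error measures), quadratic-scoring-rule
    belief payments, permutation-based inference, and a parameter-recovery
    harness, orchestrated by a reproducible simulate-rate-measure-test
    pipeline with CSV and JSON artifacts.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
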