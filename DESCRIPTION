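Package: dartscore
Title: Detection and Classification of Darting Behavior in Rodent Fear Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects discrete high-velocity "dart" events and freezing bouts in
    rodent locomotor velocity traces, registers them to fear-conditioning trial
    epochs (pre-CS, CS, shock response, post-shock), classifies animals into
    Darter and Non-darter phenotypes, and runs the associated group statistics
    (chi-square independence, Mann-Whitney U, Pearson correlation, mixed-design
    ANOVA with Sidak post-hoc comparisons). Includes a seedable synthetic-cohort
    simulator that plants ground-truth darts, freezing bouts and shock bursts so
    the whole pipeline is testable without raw video-tracking data.
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
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
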