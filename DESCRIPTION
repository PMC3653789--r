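Package: bcst
Title: Berg Card Sorting Test Simulation, Scoring and Short-Form Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable engine for the Berg Card Sorting Test (BCST), the
    open-source analogue of the Wisconsin Card Sorting Test. Builds the
    standard 128-card deck and key cards, runs full sessions against
    pluggable respondent policies, scores sessions with the Berg/PEBL-style
    perseveration criterion (total errors, perseverative responses,
    perseverative errors, categories completed, raw and percent), supports
    the 64-trial short form, simulates heterogeneous respondents with a
    win-stay/lose-shift agent model, and runs cohort-level short-form
    validation analyses (part-whole and half-vs-half Pearson correlation
    batteries with mean/SD tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
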