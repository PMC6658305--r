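Package: feverpattern
Title: Postvaccination Fever Episode Extraction and Pattern Analysis from
    Caregiver-Recorded Temperatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing postvaccination fever from irregular,
    caregiver-recorded body-temperature logs. Extracts fever episodes
    (onset, offset, duration, maximum temperature) by piecewise-linear
    imputation and threshold crossing, applies the record-selection
    cascade (single vaccinations, minimum reading counts, per-vaccine
    minimums), characterises antipyretic dosing behaviour, and runs the
    inferential battery used in this setting: Welch two-sample tests,
    one-way ANOVA with a mean-centred Levene check, Dunnett T3 post hoc
    comparisons via the studentized maximum modulus distribution, and
    logistic regression for high fever with variance-inflation-factor
    screening. A seeded synthetic cohort simulator with vaccine-specific
    fever kinetics and a caregiver dosing model makes every stage testable
    without access to proprietary app data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
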