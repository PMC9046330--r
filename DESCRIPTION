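Package: adtfalls
Title: Cost-Utility Model of Exercise for Falls Prevention During Androgen
    Deprivation Therapy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort cost-utility model of a 12-month supervised
    exercise programme versus usual care for preventing falls, fractures and
    fall injuries in men receiving androgen deprivation therapy for
    non-metastatic prostate cancer. Implements the three-monthly cycle cohort
    engine with half-cycle correction and discounting, base-case incremental
    cost-utility analysis with net monetary benefit, deterministic one-way and
    scenario sensitivity analyses, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and an individual-level
    microsimulation used as an independent validation oracle for the cohort
    engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
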