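Package: neuroequity
Title: Social Preference Models for Costly Punishment and Prefrontal
    Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a norm-compliance
    punishment game with functional near-infrared spectroscopy (fNIRS)
    recordings. Implements nine competing social-utility models
    (Fehr-Schmidt inequity aversion with and without constraints,
    efficiency and reciprocity models of Charness-Rabin type, component
    models, and response-time-enhanced variants), multi-start nonlinear
    least-squares fitting of punishment behavior, modified Beer-Lambert
    conversion and sliding-window analysis of two-wavelength optical
    recordings, robust (fair-weight) regression of hemodynamic responses,
    AIC and nested-F model comparison, percentage-bend correlations between
    behavioral and neural preference parameters, and support-vector
    regression linking prefrontal activity to punishment behavior. A seeded
    synthetic-cohort generator makes every stage testable without data
    collection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    e1071,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
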