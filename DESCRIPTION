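Package: ctclqol
Title: Rasch Calibration and Scoring for a Cutaneous T-Cell Lymphoma
    Quality-of-Life Instrument
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.com")
Description: Psychometric toolkit for developing and scoring a
    patient-reported quality-of-life instrument for mycosis fungoides /
    Sezary syndrome cutaneous T-cell lymphoma (MF/SS-CTCL). Implements
    joint maximum likelihood estimation of polytomous Rasch models (the
    Andrich rating scale model, a grouped rating scale model with separate
    threshold sets for frequency- and intensity-worded items, and the
    partial credit model), likelihood-ratio model comparison, infit/outfit
    mean-square item fit with iterative purging, principal components
    analysis of standardized residuals, rating-scale and test-information
    diagnostics, a person-to-item (Wright) map, person and item separation
    reliability, test-retest and convergent/discriminant validity,
    differential item functioning via anchored between-group contrasts,
    and raw-to-scaled score conversion including the published 12-item
    scoring table. A synthetic-response generator reproduces the
    statistical structure of the development study so the whole pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
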