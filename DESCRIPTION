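Package: fdd11
Title: Partial Credit Model Calibration and Scoring for the WHO FDD11
    Disability Instrument
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calibration and scoring of the World Health Organization
    Functioning and Disability Disaggregation tool (FDD11) and similar short
    polytomous questionnaires under the Rasch Partial Credit Model. Provides
    conditional maximum likelihood item calibration via elementary symmetric
    functions, maximum likelihood person ability estimation with standard
    errors, the published FDD11 calibration with its 0-100 disability metric
    and severity cut-offs, model diagnostics (infit mean squares, residual
    correlations, threshold ordering, targeting, person separation index),
    dimensionality assessment (polychoric correlations, parallel analysis,
    bi-factor loading comparison), differential item functioning screening,
    and a synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
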