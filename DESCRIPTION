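Package: glucoheat
Title: Noninvasive Blood Glucose Estimation from Wrist Metabolic Heat and Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates blood glucose concentration noninvasively from wrist
    sensor readings under an energy-conservation model of resting metabolism.
    Computes metabolic heat production from radiative, convective and
    evaporative heat loss; extracts heart rate and oxygen saturation from
    dual-wavelength (660/880 nm) photoplethysmography by peak detection and
    the ratio-of-ratios method; fits glucose regression models (a
    fourth-degree interaction-only polynomial and a single-hidden-layer
    tansig network trained by Levenberg-Marquardt least squares); and
    evaluates predictions with mARD, correlation, MAD, RMSE, SEP and the
    Clarke error grid. Includes a seeded synthetic-cohort simulator so the
    full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    signal,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
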