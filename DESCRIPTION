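Package: carbrisk
Title: Carbamate Residue Quantification, Method Validation and Probabilistic
    Dietary Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-acquisition computational chain for pesticide-residue
    monitoring of carbamates in food commodities: internal-standard
    calibration and quantification, limit of detection and quantification
    from blank-signal statistics, matrix-effect assessment by slope
    comparison, SANTE-style validation statistics (recovery, intraday and
    interday relative standard deviation), top-down expanded measurement
    uncertainty, screening of residue concentrations against maximum
    residue limits, and a Monte-Carlo probabilistic dietary risk
    assessment (chronic daily intake, hazard quotient, hazard index) for
    adult and child consumer profiles. Includes a synthetic-data module
    that generates every pipeline input with known ground truth, and a
    study fixture emulating a 55-sample date-fruit monitoring campaign.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
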