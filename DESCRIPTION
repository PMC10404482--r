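Package: biavalid
Title: Validation of Body-Fat Estimation Devices Against a Four-Compartment Criterion
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the statistical validation of bioelectrical impedance
    analysis (BIA) and similar body-fat-percentage devices against a laboratory
    four-compartment (4C) criterion model. Implements the 4C body-fat equation,
    test-retest reliability metrics (precision error, least significant change,
    detection of non-independent repeat readings), cross-sectional and
    longitudinal agreement statistics (constant and total error, standard error
    of the estimate, Lin's concordance correlation, ordinary least squares and
    Deming regression, Bland-Altman limits of agreement with proportional-bias
    testing, TOST equivalence), and a five-domain device-ranking system.
    Includes a synthetic-cohort generator with configurable device error models
    so the full pipeline can be exercised and tested without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
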