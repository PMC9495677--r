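Package: phenolmix
Title: Interaction Analysis of Antioxidant Phenolic-Acid Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying antioxidant interactions in equimolar
    mixtures of phenolic acids measured with the FRAP (ferric reducing
    antioxidant power) and ORAC (oxygen radical absorbance capacity) assays.
    Computes expected-additivity (theoretical) activities for k-component
    equimolar mixtures, the difference-(%) interaction index with
    delta-method uncertainty, and synergistic/additive/antagonistic
    classifications; reduces raw plate-reader data (standard-curve
    calibration, kinetic net area under the curve) to assay units; derives
    ring-substituent structure-activity features; ships the printed study
    tables of a ten-acid panel as fixtures with a reproduction report; and
    simulates full studies with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    pracma,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
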