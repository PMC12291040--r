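Package: simcascreen
Title: SIMCA Class Modeling for UPLC-HRMS/MS Drug Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds eight-variable spectral feature matrices (precursor m/z,
    retention time, the three most intense MS/MS fragments and their neutral
    losses) from centroided tandem mass spectra of drug standards, splits them
    with the Kennard-Stone maximin algorithm, explores them with PCA outlier
    diagnostics (Hotelling T-squared and Q residuals with 95 percent critical
    limits), and fits per-class SIMCA one-class models that accept or reject
    unknown analytes per drug class.  Includes cross-validated component
    selection by maximum efficiency (geometric mean of sensitivity and
    specificity), Coomans-plot distance tables for comparing structurally
    similar classes, a seeded synthetic-spectra generator for end-to-end
    testing, and a command-line pipeline for screening seized-sample spectra
    against a panel of class models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
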