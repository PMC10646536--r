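Package: dkdcompass
Title: Composite Biomarker Modelling for Drug Selection in Diabetic Kidney
    Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates a composite prognostic biomarker for
    diabetic kidney disease from longitudinal visit data. Provides a
    synthetic cohort generator emulating an observational DKD study with
    four treatment arms (RASi alone and RASi plus GLP1a, MCRa or SGLT2i),
    cohort preparation (MDRD eGFR, annual percent change in eGFR,
    controlled/uncontrolled disease labelling), partial least squares
    variable ranking with VIP scores, a hybrid PLS + normalized radial
    basis function regression model (PLSNN) whose RASi-arm prediction is
    the composite biomarker, counterfactual add-on benefit estimation as
    the vertical distance between per-arm models, treatment
    recommendation, and CD/UCD allocation diagnostics with grouped
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
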