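Package: idealclass
Title: IDEAL Classification of Distal Radius Fractures and Observer-Agreement Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements the IDEAL scoring system for distal radius fractures
    (five binary items - joint Incongruity, Displacement, trauma Energy, Age,
    associated Lesions - summing to a 0-5 score mapped to three fracture types
    with treatment and prognosis guidance), together with the statistical
    machinery of classification reproducibility studies: Cohen's kappa for two
    raters, Fleiss's multi-rater kappa, intra- and interobserver agreement
    from long-format rating tables, kappa interpretation bands, cross-system
    comparison by one-way F tests, and agreement-study sample size by the
    expected confidence-interval-width method of Giraudeau and Mary. A
    synthetic multi-observer rating simulator with confusion-matrix observer
    error, measurement noise and within-observer session correlation provides
    ground-truth data for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
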