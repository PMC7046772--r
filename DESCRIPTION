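Package: pnms
Title: Principal-Network Analysis of Structural Brain Connectomes in
    Multiple Sclerosis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing weighted structural brain connectomes in
    multiple sclerosis cohorts: nodal-strength hub detection on group-mean
    connectivity matrices, eigendecomposition-based principal-network (PN)
    extraction with loading thresholding, healthy-control-referenced
    subnetwork strength metrics, and covariate-adjusted regression models
    linking subnetwork strengths to clinical disability scores (EDSS, SDMT).
    Includes a calibrated synthetic-cohort generator that emulates the
    statistical structure of a 115-region multiple-sclerosis connectome
    study, so the full pipeline is testable without access to subject-level
    imaging data, plus readers and writers for plain-text connectome,
    node-table and cohort-manifest formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
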