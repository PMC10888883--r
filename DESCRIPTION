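Package: metquilt
Title: Post-Processing, Annotation and Quality Control for LC-MS Metabolomics Feature Tables
Version: 0.1.0
Authors@R: person("Metquilt", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Common data models for LC-MS metabolomics (features, empirical
    compounds, experiments) with lossless JSON serialization, and a chainable
    post-preprocessing pipeline: grouping of isotopologues and adducts into
    empirical-compound grids with neutral-mass inference, multi-level
    annotation (neutral-mass lookup, authentic-standard m/z and retention
    time matching, tandem spectral similarity with an indexed precursor
    search), quality control of feature tables (TIC normalization, blank
    masking, rare-feature removal, imputation, failed-injection detection,
    empirical-Bayes batch correction, PCA and correlation summaries), and
    standardized three-table plus JSON outputs driven by a command-line
    front end with provenance logging. Includes seed-deterministic synthetic
    data generators with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
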