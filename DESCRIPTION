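Package: herbfp
Title: HPLC-ELSD Fingerprinting, Chemometrics and Single-Marker
    Quantification for Herbal Quality Evaluation
Version: 0.1.0
Authors@R:
    person("herbfp", "developers", email = "herbfp@example.org",
           role = c("aut", "cre"))
Description: Tools for quality evaluation of herbal materials from
    HPLC-ELSD chromatographic fingerprints: a synthetic chromatogram and
    calibration-series generator, peak detection and integration with
    noise and LOD/LOQ estimation, retention-time correction and
    common-peak matching into standardized fingerprints with cosine
    similarity scoring, chemometrics (PCA, hierarchical clustering,
    OPLS-DA with VIP scores and permutation validation), and quantitative
    analysis of multi-components by a single marker (QAMS) via relative
    correction factors, with external-standard cross-validation,
    durability analysis and method-validation statistics. A
    configuration-driven pipeline ties the stages together and writes
    reproducible report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
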