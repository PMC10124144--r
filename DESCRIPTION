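Package: shapMSI
Title: Shapley-Value Guided Biomarker Candidate Discovery for Imaging Mass Spectrometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated discovery of molecular marker candidates in peak-picked
    imaging mass spectrometry (IMS) data. Pixels are classified into
    user-annotated tissue classes with gradient-boosted regression trees
    trained on the logistic loss, and every pixel x m/z feature pair receives
    an exact observational (tree-path-dependent) Shapley value on the
    log-odds scale. Features are ranked by global SHAP score and per-feature
    SHAP maps localise where in the tissue each candidate marker drives the
    classifier, distinguishing correlative from anticorrelative markers.
    Includes a synthetic phantom generator with planted markers, correlated
    feature pairs and an artifact-bleed confound, brute-force Shapley oracles
    for verification, and a configuration-driven command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'shapMSI-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'ims_data.R'
    'phantom.R'
    'boosting.R'
    'serialize.R'
    'shapley.R'
    'shap_maps.R'
    'pipeline.R'
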