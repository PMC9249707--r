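Package: clehom
Title: Objective Tissue-Homogeneity Analysis for Confocal Laser Endomicroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify tissue homogeneity in probe-based confocal
    laser endomicroscopy (CLE) of laryngeal and hypopharyngeal mucosa. Mean
    gray values are measured in four 45x45 micrometre corner regions of
    interest of every frame of a 60-frame sequence; the mean across-ROI
    standard deviation summarizes regional inhomogeneity and separates
    benign honeycomb epithelium from squamous cell carcinoma. Includes
    fluorescein wash-in (flooding) onset detection on kinetic traces, a
    calibrated synthetic CLE sequence generator (honeycomb and carcinoma
    textures, wash-in kinetics, an artifact compositor, simulated raters)
    for fully reproducible end-to-end runs, and observer-study statistics:
    sensitivity and specificity with Wilson score confidence intervals,
    Pearson chi-square on 2x2 tables, Welch t-tests, and Fleiss kappa with
    Landis-Koch interpretation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
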