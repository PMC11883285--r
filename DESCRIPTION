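Package: geotrack
Title: Multi-Fly Tracking and Analytics for Drosophila Negative Geotaxis Assays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calibration-driven detection and Kalman/Hungarian multi-object
    tracking of Drosophila melanogaster in backlit climbing-assay videos,
    producing per-fly trajectories at frame resolution, together with the
    behavioral analytics used to quantify negative geotaxis: climbing curves,
    frame-to-frame speed and movement-angle kinematics, bootstrapped
    directional-bias correlation ratios, and slip/fall event detection. A
    synthetic-video simulator with known ground truth and an accuracy
    evaluator provide a self-contained benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    clue,
    png,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
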