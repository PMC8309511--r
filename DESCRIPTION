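Package: gazeparse
Title: Gaze Event Detection, Behavior-Based Stare/Move Classification, and
    Multi-Level Gaze Visualization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for parsing screen-based eye-tracking recordings into
    oculomotor events and visualizing them at several levels of abstraction.
    Implements the classical fixation/smooth-pursuit detectors I-VT, I-DT,
    DBSCAN with interquartile-range epsilon selection, and I-VDT; a
    behavior-based stare/move classifier that rasterizes sliding gaze windows
    into grayscale images and trains small convolutional networks on them;
    fixation-count heatmaps, scanpaths, and a time-layered abstract
    gaze-movement rendering with tapered, color-graded movement links; the
    FQnS/FQlS fixation scores, smooth-pursuit position/velocity scores,
    range-coefficient parameter sweeps, and per-class sample-level F1 used to
    compare detectors; and a seeded oculomotor simulator (tremor,
    microsaccades, drift, main-sequence saccades, pursuit with catch-up
    saccades, binocular dropouts) that generates ground-truthed recordings for
    testing every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
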