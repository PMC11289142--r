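Package: beamtrack
Title: Marker Tracking and Closed-Loop Laser Targeting for Optogenetic
    Illumination Rigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Software stack of a portable camera-guided blue-light illumination rig for
    optogenetic experiments on freely moving rodents: colour-mask
    segmentation, morphological cleanup and frame-by-frame centroid tracking
    of a pen-marked site from overhead video; planar homography calibration
    between image pixels and the cage floor; pan/tilt gimbal geometry that
    points a laser at the tracked site; an illumination scheduler with exact
    light/dark-cycle dose accounting; and a closed-loop simulator with a
    synthetic-scene generator that emits ground truth, so the whole pipeline
    is exercisable and testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tibble,
    dplyr,
    purrr,
    generics,
    ggplot2,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
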