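Package: animtrack
Title: Colour-Threshold Video Tracking and Kinematic Analysis of Single Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks one high-contrast animal (or one colour tag) per video by
    HSV colour thresholding and largest-connected-object detection, recording
    the contour centroid and the minimum rotated rectangle (length, width,
    angle) at every frame. Downstream kinematics include total path length,
    instantaneous velocity over fixed frame windows, step-distance binning,
    rectangular-region occupancy, segment-wise coefficient of variation of
    travel distance, path normalisation, and a larval stride/turn classifier
    driven by the body-length trace and the length:width aspect ratio.
    Ships a deterministic synthetic-video generator (moving discs, pulsating
    ellipses, salt noise) with exact ground truth, a batch command-line
    front end, and plain-text preset/settings/summary file formats. Video
    input and output use uncompressed RGB AVI containers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
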