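Package: synthrig
Title: Procedural Synthetic Training Data for Animal Detection, Tracking and Pose Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates annotated synthetic image datasets of articulated
    animal models placed in procedurally randomized scenes, following a
    domain-randomization strategy: terrain built from procedural RGB control
    maps, scattered untextured assets, randomized lighting and cameras, and
    subjects posed by ray-cast foot targets with joint-limited inverse
    kinematics. A deterministic software rasterizer produces co-registered
    render, instance-ID, depth and surface-normal passes from which bounding
    boxes, 2D/3D keypoints, occlusion flags and occupancy are derived and
    written to machine-readable annotation files. Exporters translate
    datasets to YOLO, COCO (boxes, keypoints, instance masks), flat keypoint
    tables, segmentation label maps and a camera-aware 3D pose format. Also
    included are a detection-based buffer-and-recover multi-animal tracker
    (constant-velocity Kalman filtering with Hungarian association) and the
    matching evaluation statistics: centre-based average precision, mean
    average precision, multiple-object tracking accuracy with identity-switch
    bookkeeping, relative pose error, and average class-wise recall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jpeg,
    withr
Config/testthat/edition: 3
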