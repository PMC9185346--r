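Package: gaitnorm
Title: Normalization and Evaluation of 2D Gait Skeleton Keypoint Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for making distance-based gait features comparable across
    frames of freehand single-camera video. Reads pose-estimator keypoint
    output in the AlphaPose COCO-17 dialect, cleans low-confidence frames,
    applies a two-step skeleton normalization (mid-shoulder position shifting
    followed by size scaling) with seven scaling-method variants, and
    evaluates the result with mean absolute joint-angle error, inter-keypoint
    distance variance, keypoint dispersion summaries, and nonparametric group
    comparisons. Includes a seeded synthetic gait simulator (weak-perspective
    camera model with scale ramps, handheld jitter, keypoint noise, confidence
    scores and dropout) so every stage can be exercised with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
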