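Package: camfuse
Title: Multi-Camera Bounding-Box Fusion and Fuzzy Confidence Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Scores the trustworthiness of object-detector bounding boxes seen
    by a two-camera rig. A planar homography estimated from point
    correspondences (direct linear transform with least-mean-square, RANSAC or
    least-median-of-squares optimisation) reprojects one camera's boxes onto
    the other's image plane; the intersection-over-union overlap of the
    reprojected box pair, together with the vertical position of each box, is
    fused through a Mamdani fuzzy rule base with centroid defuzzification into
    a per-frame confidence score between 0 and 100 percent. Includes a
    synthetic stereo pinhole scene generator for calibrating the
    overlap-versus-distance anchors and for end-to-end testing, plus a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
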