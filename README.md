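# camfuse

Multi-camera bounding-box fusion with fuzzy confidence scoring.

A convolutional object detector can draw a confidently-scored bounding box
that nonetheless misses the object — the classifier score says nothing about
whether the box is in the right *place*. `camfuse` cross-checks detections
between two cameras viewing the same scene: because the object occupies one
position in 3D space, the geometric relationship between the two boxes is
constrained, and a frame whose boxes violate that constraint deserves less
trust no matter what the detector reported. The package targets agricultural
settings (the bundled examples score weed detections — cocklebur, pigweed,
ragweed — from a two-camera rig), but nothing in it is crop-specific.

## The method

1. **Planar homography.** The two image planes are related, for coplanar
   world points, by a non-singular 3×3 matrix *H* with 8 degrees of freedom
   (`h33 = 1`): a point `(x, y)` on the left plane maps to
   `x' = (h11 x + h12 y + h13)/w`, `y' = (h21 x + h22 y + h23)/w`,
   `w = h31 x + h32 y + h33`. `estimate_homography()` solves for *H* from ≥ 4
   checkerboard-corner correspondences by the normalized direct linear
   transform, optimized under least-mean-square, RANSAC, or
   least-median-of-squares criteria (the robust two survive up to ~30–50%
   gross outliers). The fit reports its mean Euclidean reprojection error in
   pixels per corner point.
2. **Reprojection + IOU.** Per frame, each camera's detections pass through
   non-maximum suppression; the left box is reprojected through *H* onto the
   right plane and its intersection-over-union overlap with the right box is
   measured. For perfect detections this overlap is a known, calibratable
   function of object distance — it shrinks as the object approaches,
   because a 3D object sits farther from the homography's calibration plane.
3. **Mamdani fuzzy fusion.** Three crisp inputs — the right box's vertical
   center (px), the left box's vertical center (px), and the reprojected IOU
   (%) — enter a 20-rule Mamdani system over four distance classes
   (*too far*, *far*, *close*, *too close*). Matched positions with the
   expected overlap conclude **High** (4 rules); mismatched positions
   conclude **Low** (12 rules); matched positions whose overlap is *Not* the
   expected one conclude **OK** (4 rules with negated antecedents).
   Activation is min over antecedents, implication clips the consequent,
   aggregation is pointwise max, and centroid defuzzification yields a
   0–100% confidence score per frame.

## Worked example

```r
library(camfuse)

cfg   <- camfuse_config()                       # default anchors, 15% close-class IOU
frame <- generate_scenario("high", seed = 1, config = cfg)
frame
#> <synthetic_frame> kind: high | class: too_close | seed: 1
#>   left  <bounding_box> [919.15, 1419.15] x [425, 775] (500 x 350 px)
#>   right <bounding_box> [-139.15, 360.85] x [425, 775] (500 x 350 px)

score_frame(frame$left, frame$right, frame$homography, cfg)
#> <confidence_result> score 90.0% (high) | reprojected IOU 0.0%
#>   fired: R4=1
```

Both boxes sit with their vertical centers on the too-close anchor (600 px)
and the reprojected overlap equals the calibrated too-close anchor, so only
rule R4 — all three inputs matched at *too close* — fires, at full
activation. The centroid of the High output set gives 90.0%: perfect frames
score high but never exactly 100, a built-in property of centroid
defuzzification. A laterally-offset left box instead fires R20 and scores
exactly 50.0% ("ok"); a left box at the wrong height fires R15 and scores
10.0% ("low").

Homography estimation from noisy synthetic checkerboard corners:

```r
cs  <- generate_correspondences(default_stereo_rig(), grid = c(9, 6),
                                noise_sigma = 1, seed = 42)
estimate_homography(cs, "ransac", params = list(seed = 7))
#> <homography_fit> method: ransac | reprojection error: 1.59955 px/point | inliers: 50/54
```

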