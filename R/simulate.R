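#' Pinhole camera model
#'
#' An ideal (distortion-free) pinhole camera: a world point (X, Y, Z), taken
#' relative to the camera center with Z along the optical axis, projects onto
#' the image plane at `x = f X / Z + cx`, `y = f Y / Z + cy`. All cameras in a
#' rig share orientation (fronto-parallel), so only the camera center's world
#' offset differs between views.
#'
#' @param f focal length in pixel units (> 0).
#' @param principal_point `c(cx, cy)` image-plane offset in pixels.
#' @param image_size `c(width, height)` in pixels.
#' @param position 3D world offset `c(X, Y, Z)` of the camera center (world
#'   units, e.g. inches).
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(f, principal_point = c(0, 0),
                         image_size = c(1280, 720), position = c(0, 0, 0)) {
  if (!is.finite(f) || f <= 0) stop("focal length must be positive", call. = FALSE)
  structure(list(f = f, principal_point = as.numeric(principal_point),
                 image_size = as.numeric(image_size),
                 position = as.numeric(position)),
            class = "camera_model")
}

# project world points (n x 3, absolute world coordinates) into a camera
pinhole_project <- function(cam, pts) {
  pts <- if (is.null(dim(pts))) matrix(pts, 1, 3) else as.matrix(pts)
  rel <- sweep(pts, 2, cam$position)
  if (any(rel[, 3] <= 0)) stop("point is not in front of the camera (Z <= 0)", call. = FALSE)
  cbind(cam$f * rel[, 1] / rel[, 3] + cam$principal_point[1],
        cam$f * rel[, 2] / rel[, 3] + cam$principal_point[2])
}

#' Two-camera rig with a horizontal baseline
#'
#' Both cameras share intrinsics and orientation and are separated by a
#' horizontal baseline; a world plane at `calibration_depth` induces the
#' ground-truth homography between the two views (for this fronto-parallel
#' geometry, a pure horizontal pixel translation by `f * baseline / depth`).
#'
#' @param f shared focal length in pixels.
#' @param baseline camera separation in world units (> 0 unless building a
#'   degenerate test rig).
#' @param image_size `c(width, height)` pixels.
#' @param principal_point `c(cx, cy)` pixels; default image center.
#' @param calibration_depth depth of the checkerboard/calibration plane in
#'   world units.
#' @return an object of class `stereo_rig` with cameras `left` (centered at
#'   `-baseline/2`) and `right` (`+baseline/2`).
#' @export
stereo_rig <- function(f, baseline, image_size = c(1280, 720),
                       principal_point = image_size / 2,
                       calibration_depth = 36) {
  if (baseline < 0) stop("baseline must be non-negative", call. = FALSE)
  if (calibration_depth <= 0) stop("calibration plane must be in front of the cameras", call. = FALSE)
  structure(list(
    left = camera_model(f, principal_point, image_size, c(-baseline / 2, 0, 0)),
    right = camera_model(f, principal_point, image_size, c(baseline / 2, 0, 0)),
    baseline = baseline, f = f, image_size = as.numeric(image_size),
    principal_point = as.numeric(principal_point),
    calibration_depth = calibration_depth
  ), class = "stereo_rig")
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat(sprintf("<stereo_rig> f = %g px, baseline = %g, image %g x %g, calibration plane at depth %g\n",
              x$f, x$baseline, x$image_size[1], x$image_size[2], x$calibration_depth))
  invisible(x)
}

#' The default simulated rig
#'
#' A parallel fronto-facing two-camera rig on a 1280 x 720 view with focal
#' length 1400 px and the calibration plane at the too-far depth (36 in). The
#' baseline is solved in closed form so that a perfect fixed-size detection
#' pair at the close-class depth, reprojected through the rig's ground-truth
#' homography, overlaps by exactly 15% IOU — the one overlap anchor the
#' membership design pins down. With the default 500 x 350 px boxes this
#' gives a baseline of about 6 in.
#'
#' @param depths named depths (world units, inches) of the four distance
#'   classes, decreasing from `too_far` to `too_close`.
#' @param box_width,box_height fixed detection-box size in pixels.
#' @param close_iou the pinned close-class after-reprojection IOU fraction.
#' @param f focal length in pixels.
#' @return a [stereo_rig()].
#' @export
default_stereo_rig <- function(depths = c(too_far = 36, far = 22, close = 14,
                                          too_close = 8),
                               box_width = 500, box_height = 350,
                               close_iou = 0.15, f = 1400) {
  z_plane <- depths[["too_far"]]
  # horizontal center offset giving the target IOU for equal-size boxes
  delta <- box_width * (1 - close_iou) / (1 + close_iou)
  fb <- delta / (1 / depths[["close"]] - 1 / z_plane)
  rig <- stereo_rig(f = f, baseline = fb / f, calibration_depth = z_plane)
  rig$depths <- depths
  rig$box_width <- box_width
  rig$box_height <- box_height
  rig
}

#' Object pose in the simulated scene
#'
#' @param center world coordinates `c(X, Y, Z)` of the object center, Z > 0.
#' @param width,height physical extent of the fronto-planar object patch
#'   (world units).
#' @param class_label optional distance-class name derived from Z.
#' @return an object of class `scene_pose`.
#' @export
scene_pose <- function(center, width = 5, height = 3.5, class_label = NULL) {
  center <- as.numeric(center)
  if (length(center) != 3 || !all(is.finite(center))) {
    stop("pose center must be a finite (X, Y, Z) triple", call. = FALSE)
  }
  if (center[3] <= 0) stop("object must be in front of the cameras (Z > 0)", call. = FALSE)
  structure(list(center = center, width = width, height = height,
                 class_label = class_label),
            class = "scene_pose")
}

# pose whose projected vertical box center lands on `anchor_y` in both views
pose_for_class <- function(rig, class, anchor_y) {
  z <- rig$depths[[class]]
  y_world <- (anchor_y - rig$principal_point[2]) * z / rig$f
  scene_pose(c(0, y_world, z), class_label = class)
}

#' Project an object pose into a camera
#'
#' With `policy = "physical"` the fronto-planar object patch is projected
#' exactly: the box spans `f * width / Z` by `f * height / Z` pixels around
#' the projected centroid. With `policy = "fixed"` a constant-size detector
#' box (`width_px` x `height_px`) is centered on the projected centroid,
#' mirroring a detector that draws same-size boxes at every distance.
#'
#' @param cam a [camera_model()].
#' @param pose a [scene_pose()].
#' @param policy `"physical"` or `"fixed"`.
#' @param width_px,height_px fixed box size in pixels for `policy = "fixed"`.
#' @return a [bounding_box()].
#' @export
render_box <- function(cam, pose, policy = c("physical", "fixed"),
                       width_px = 500, height_px = 350) {
  policy <- match.arg(policy)
  ctr <- pinhole_project(cam, pose$center)
  if (policy == "physical") {
    z <- pose$center[3] - cam$position[3]
    w <- cam$f * pose$width / z
    h <- cam$f * pose$height / z
  } else {
    w <- width_px
    h <- height_px
  }
  box_from_center(ctr[1], ctr[2], w, h)
}

#' Ground-truth homography induced by the calibration plane
#'
#' Maps left-camera pixels of world points lying on the plane
#' `Z = plane_depth` onto their right-camera pixels. For this rig's
#' fronto-parallel geometry that map is a pure horizontal translation by
#' `-f * baseline / plane_depth` pixels; it is exact only for points on the
#' plane, which is what makes reprojected overlap distance-dependent for
#' objects off the plane.
#'
#' @param rig a [stereo_rig()].
#' @param plane_depth depth of the inducing plane (default the rig's
#'   calibration depth).
#' @return the left-to-right [homography()].
#' @export
ground_truth_homography <- function(rig, plane_depth = rig$calibration_depth) {
  if (plane_depth <= 0) stop("plane must be in front of both cameras", call. = FALSE)
  shift <- -rig$f * rig$baseline / plane_depth
  homography(rbind(c(1, 0, shift), c(0, 1, 0), c(0, 0, 1)))
}

#' Generate checkerboard-like correspondences between the two views
#'
#' An n x m grid of coplanar world points at `plane_depth` is projected into
#' both cameras. Optional seeded Gaussian pixel noise perturbs the measured
#' corner locations in both views, and a seeded fraction of rows can be
#' replaced by gross outliers (uniform mislocations on the target plane).
#'
#' @param rig a [stereo_rig()].
#' @param plane_depth depth of the board (default the calibration depth).
#' @param grid `c(n, m)` corners across and down; `n * m >= 4`.
#' @param noise_sigma pixel standard deviation of corner measurement noise
#'   applied independently in each view (0 = exact).
#' @param outlier_fraction fraction of correspondences replaced by gross
#'   outliers.
#' @param seed integer seed controlling noise and outliers.
#' @param extent world-unit half-extent of the board (default sized to fill
#'   about half the view).
#' @return a [correspondences()] table with attribute `outlier_true` flagging
#'   the injected outliers.
#' @export
generate_correspondences <- function(rig, plane_depth = rig$calibration_depth,
                                     grid = c(9, 6), noise_sigma = 0,
                                     outlier_fraction = 0, seed = 1,
                                     extent = NULL) {
  if (prod(grid) < 4) stop("grid must contain at least 4 corners", call. = FALSE)
  if (is.null(extent)) {
    extent <- 0.25 * rig$image_size[1] * plane_depth / rig$f
  }
  gx <- seq(-extent, extent, length.out = grid[1])
  gy <- seq(-extent * grid[2] / grid[1], extent * grid[2] / grid[1],
            length.out = grid[2])
  world <- cbind(rep(gx, times = grid[2]), rep(gy, each = grid[1]), plane_depth)
  pl <- pinhole_project(rig$left, world)
  pr <- pinhole_project(rig$right, world)
  n <- nrow(world)
  outlier_true <- rep(FALSE, n)
  with_local_seed(seed, {
    if (noise_sigma > 0) {
      pl <- pl + matrix(stats::rnorm(2 * n, sd = noise_sigma), n, 2)
      pr <- pr + matrix(stats::rnorm(2 * n, sd = noise_sigma), n, 2)
    }
    n_out <- round(outlier_fraction * n)
    if (n_out > 0) {
      idx <- sample.int(n, n_out)
      outlier_true[idx] <- TRUE
      pr[idx, 1] <- stats::runif(n_out, 0, rig$image_size[1])
      pr[idx, 2] <- stats::runif(n_out, 0, rig$image_size[2])
    }
  })
  cs <- correspondences(pl[, 1], pl[, 2], pr[, 1], pr[, 2])
  attr(cs, "outlier_true") <- outlier_true
  cs
}

#' Calibrate the IOU-versus-distance anchors
#'
#' For each distance class, perfect fixed-size detection boxes are rendered in
#' both views, the left box is reprojected through the rig's ground-truth
#' homography, and the overlap with the right box is measured. The returned
#' percentages serve as the peaks of the IOU membership functions: overlap
#' grows with distance because the object sits ever closer to the calibration
#' plane that induces the homography.
#'
#' @param rig a rig from [default_stereo_rig()] (must carry class `depths`
#'   and a box policy).
#' @param reproject if `FALSE`, measure the raw overlap without reprojection
#'   (for before/after comparisons).
#' @return named numeric: IOU percent per class, ordered `too_far` down to
#'   `too_close`.
#' @export
calibrate_iou_anchors <- function(rig, reproject = TRUE) {
  if (is.null(rig$depths)) stop("rig carries no distance-class depths", call. = FALSE)
  h <- ground_truth_homography(rig)
  anchors <- vapply(names(rig$depths), function(cl) {
    pose <- pose_for_class(rig, cl, rig$image_size[2] / 2)
    bl <- render_box(rig$left, pose, "fixed", rig$box_width, rig$box_height)
    br <- render_box(rig$right, pose, "fixed", rig$box_width, rig$box_height)
    if (reproject) bl <- project_box(h, bl)
    100 * iou(bl, br)
  }, numeric(1))
  anchors
}

#' Generate a synthetic scored frame
#'
#' Builds a two-camera frame at one of three scripted scenarios for a given
#' distance class:
#'
#' * `"high"` — both detectors box the object perfectly.
#' * `"ok"` — vertical centers are correct in both views, but the left
#'   detection is displaced laterally (toward the left, as when a detector
#'   locks onto the object's left edge), so the reprojected overlap departs
#'   from its calibrated anchor.
#' * `"low"` — the left detection sits at the wrong height: its vertical
#'   center lands on a different distance class's anchor (default `far` when
#'   the true class is `too_close`, the mismatch that fires rule R15).
#'
#' Optional seeded jitter perturbs box centers and sizes to emulate detector
#' noise; with `jitter_sigma = 0` the frame is fully deterministic.
#'
#' @param kind `"high"`, `"ok"` or `"low"`.
#' @param rig a [default_stereo_rig()]-style rig.
#' @param seed integer seed (drives the jitter; recorded in the frame).
#' @param config a [camfuse_config()] providing the distance anchors; default
#'   configuration if omitted.
#' @param class true distance class of the object (default `"too_close"`,
#'   the position exercised in the scoring scenarios).
#' @param jitter_sigma pixel standard deviation of center/size jitter.
#' @return an object of class `synthetic_frame`: list with `left`, `right`
#'   ([detection()]s), `homography`, `kind`, `class`, `seed`.
#' @export
generate_scenario <- function(kind = c("high", "ok", "low"),
                              rig = default_stereo_rig(), seed = 1,
                              config = NULL, class = "too_close",
                              jitter_sigma = 0) {
  kind <- match.arg(kind)
  if (is.null(config)) config <- camfuse_config(rig = rig)
  if (!class %in% names(rig$depths)) stop("unknown distance class", call. = FALSE)
  h <- ground_truth_homography(rig)
  anchor_y <- config$distance_anchors$right[[class]]
  pose <- pose_for_class(rig, class, anchor_y)
  br <- render_box(rig$right, pose, "fixed", rig$box_width, rig$box_height)
  bl <- render_box(rig$left, pose, "fixed", rig$box_width, rig$box_height)

  if (kind == "ok") {
    # shift the left detection laterally until the reprojected overlap sits
    # mid-universe, far from every matched-class anchor
    target <- 0.5
    delta_target <- rig$box_width * (1 - target) / (1 + target)
    current <- box_center_x(project_box(h, bl)) - box_center_x(br)
    new_offset <- if (current >= 0) delta_target else -delta_target
    shift <- new_offset - current
    bl <- bounding_box(bl$x_min + shift, bl$y_min, bl$x_max + shift, bl$y_max)
  } else if (kind == "low") {
    wrong <- if (class == "far") "too_far" else "far"
    wrong_y <- config$distance_anchors$left[[wrong]]
    dy <- wrong_y - vertical_center(bl)
    bl <- bounding_box(bl$x_min, bl$y_min + dy, bl$x_max, bl$y_max + dy)
  }

  if (jitter_sigma > 0) {
    bl <- with_local_seed(seed, jitter_box(bl, jitter_sigma))
    br <- with_local_seed(seed + 1L, jitter_box(br, jitter_sigma))
  }
  structure(list(
    left = detection(bl, label = "weed", score = 1),
    right = detection(br, label = "weed", score = 1),
    homography = h, kind = kind, class = class, seed = as.integer(seed)
  ), class = "synthetic_frame")
}

box_center_x <- function(b) (b$x_min + b$x_max) / 2

jitter_box <- function(b, sigma) {
  d <- stats::rnorm(4, sd = sigma)
  w <- max(b$x_max - b$x_min + d[3], 1)
  h <- max(b$y_max - b$y_min + d[4], 1)
  box_from_center((b$x_min + b$x_max) / 2 + d[1],
                  (b$y_min + b$y_max) / 2 + d[2], w, h)
}

#' @export
print.synthetic_frame <- function(x, ...) {
  cat(sprintf("<synthetic_frame> kind: %s | class: %s | seed: %d\n",
              x$kind, x$class, x$seed))
  cat("  left  "); print(x$left$box)
  cat("  right "); print(x$right$box)
  invisible(x)
}
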