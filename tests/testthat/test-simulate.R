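rig <- default_stereo_rig()

test_that("render_box projects the pinhole equations exactly", {
  cam <- camera_model(f = 1, principal_point = c(0, 0), position = c(0, 0, 0))
  pose <- scene_pose(c(2, 0, 2), width = 0, height = 0)
  b <- render_box(cam, pose)
  expect_equal((b$x_min + b$x_max) / 2, 1)  # x = f X / Z

  # box corners equal the projected corners of the physical patch
  cam2 <- camera_model(f = 1400, principal_point = c(640, 360),
                       position = c(3, -1, 0))
  pose2 <- scene_pose(c(0.5, 2, 14), width = 5, height = 3.5)
  b2 <- render_box(cam2, pose2)
  corner <- function(dx, dy) {
    p <- pose2$center + c(dx, dy, 0) - cam2$position
    c(1400 * p[1] / p[3] + 640, 1400 * p[2] / p[3] + 360)
  }
  tl <- corner(-2.5, -1.75); br <- corner(2.5, 1.75)
  expect_equal(c(b2$x_min, b2$y_min, b2$x_max, b2$y_max),
               c(tl[1], tl[2], br[1], br[2]), tolerance = 1e-12)

  # doubling the depth halves the projected size
  near <- render_box(cam2, scene_pose(c(0, 0, 10)))
  far <- render_box(cam2, scene_pose(c(0, 0, 20)))
  expect_equal(far$x_max - far$x_min, (near$x_max - near$x_min) / 2)
  expect_equal(far$y_max - far$y_min, (near$y_max - near$y_min) / 2)

  expect_error(scene_pose(c(0, 0, -2)), "front")
})

test_that("stereo disparity between the two views is f * baseline / Z", {
  pose <- scene_pose(c(0.3, -0.2, 11))
  bl <- render_box(rig$left, pose)
  br <- render_box(rig$right, pose)
  disp <- (bl$x_min + bl$x_max) / 2 - (br$x_min + br$x_max) / 2
  expect_equal(disp, rig$f * rig$baseline / 11, tolerance = 1e-12)
  # same height in both views
  expect_equal(bl$y_min, br$y_min)
})

test_that("the plane-induced homography is the expected translation", {
  expect_equal(as.numeric(ground_truth_homography(stereo_rig(700, 0))),
               as.numeric(diag(3)))
  h <- ground_truth_homography(stereo_rig(700, 0.1), plane_depth = 7)
  expect_equal(unclass(h)[1, 3], -10)  # f B / Z = 10 px shift
  expect_error(ground_truth_homography(rig, plane_depth = -2), "front")
})

test_that("coplanar grids rendered in both views recover the ground truth", {
  h_true <- ground_truth_homography(rig)
  cs <- generate_correspondences(rig, grid = c(5, 4))
  for (method in c("least_mean_square", "ransac", "least_median_square")) {
    fit <- estimate_homography(cs, method, params = list(seed = 5))
    expect_lt(reprojection_error(fit$homography, cs), 1e-6)
    expect_equal(as.numeric(fit$homography), as.numeric(h_true),
                 tolerance = 1e-6)
  }
})

test_that("correspondence generation is seeded and reproducible", {
  a <- generate_correspondences(rig, grid = c(6, 5), noise_sigma = 1,
                                outlier_fraction = 0.2, seed = 42)
  b <- generate_correspondences(rig, grid = c(6, 5), noise_sigma = 1,
                                outlier_fraction = 0.2, seed = 42)
  expect_identical(a, b)
  c2 <- generate_correspondences(rig, grid = c(6, 5), noise_sigma = 1, seed = 43)
  expect_false(identical(a$x2, c2$x2))
  expect_error(generate_correspondences(rig, grid = c(1, 3)), "at least 4")
  # generation leaves the session RNG untouched
  set.seed(1); before <- .Random.seed
  invisible(generate_correspondences(rig, noise_sigma = 1, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("calibrated IOU anchors are monotone and pinned at the close class", {
  anchors <- calibrate_iou_anchors(rig)
  expect_equal(unname(anchors[["close"]]), 15, tolerance = 1e-9)
  ordered <- anchors[c("too_close", "close", "far", "too_far")]
  expect_true(all(diff(ordered) > 0))
  before <- calibrate_iou_anchors(rig, reproject = FALSE)
  expect_true(all(anchors >= before - 1e-12))
  # a zero-baseline rig sees identical views: every anchor is 100%
  rig0 <- default_stereo_rig()
  rig0$baseline <- 0
  rig0$left$position <- c(0, 0, 0); rig0$right$position <- c(0, 0, 0)
  expect_equal(unname(calibrate_iou_anchors(rig0)), rep(100, 4))
})

test_that("scenario frames are deterministic and carry exact geometry", {
  f1 <- generate_scenario("high", rig, seed = 7)
  f2 <- generate_scenario("high", rig, seed = 7)
  expect_identical(f1, f2)
  expect_identical(jsonlite::toJSON(unclass(f1$left$box), digits = NA),
                   jsonlite::toJSON(unclass(f2$left$box), digits = NA))
  # ground-truth boxes are exact pinhole projections: the right box center
  # sits on the configured distance anchor
  cfg <- camfuse_config(rig = rig)
  expect_equal(vertical_center(f1$right$box),
               unname(cfg$distance_anchors$right[["too_close"]]),
               tolerance = 1e-9)
  # jitter is seeded too
  j1 <- generate_scenario("high", rig, seed = 3, jitter_sigma = 2)
  j2 <- generate_scenario("high", rig, seed = 3, jitter_sigma = 2)
  expect_identical(j1, j2)
  expect_false(identical(j1$left$box,
                         generate_scenario("high", rig, seed = 4,
                                           jitter_sigma = 2)$left$box))
})

test_that("scenario kinds produce their defining geometry", {
  cfg <- camfuse_config(rig = rig)
  h <- ground_truth_homography(rig)
  ok <- generate_scenario("ok", rig, config = cfg)
  # vertical centers both still at the too-close anchor
  expect_equal(vertical_center(ok$left$box), 600, tolerance = 1e-9)
  expect_equal(vertical_center(ok$right$box), 600, tolerance = 1e-9)
  # but the reprojected overlap departed from the anchor toward mid-universe
  expect_equal(100 * iou(project_box(h, ok$left$box), ok$right$box), 50,
               tolerance = 1e-9)
  lo <- generate_scenario("low", rig, config = cfg)
  expect_equal(vertical_center(lo$left$box), 300, tolerance = 1e-9)  # far anchor
  expect_equal(vertical_center(lo$right$box), 600, tolerance = 1e-9)
})
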