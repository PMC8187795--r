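#' Configuration of the confidence-scoring system
#'
#' Collects every tunable of the fuzzy fusion pipeline. The defaults encode
#' the two anchors the membership design pins down — the too-far boxes sit
#' with their vertical center 150 px from the top of the view, and a perfect
#' close-class detection pair overlaps by 15% IOU after reprojection — and
#' derive everything else from the simulated rig:
#'
#' * distance anchors: membership peaks at 150/300/450/600 px (too far, far,
#'   close, too close) on a 720-px-high view, identical for both cameras; the
#'   triangular sets form a Ruspini partition (each set's feet at the
#'   neighboring peaks, shoulder plateaus at the universe ends).
#' * IOU anchors: Gaussian means calibrated from `rig` via
#'   [calibrate_iou_anchors()] (close class pinned to 15%); each sigma is
#'   chosen so the Gaussian crosses degree 0.5 halfway to its nearest
#'   neighboring anchor (`sigma = gap / (2 sqrt(2 ln 2))`).
#' * output sets on the 0-100% confidence universe: low = triangular(0, 0,
#'   30), ok = triangular(30, 50, 70), high = triangular(70, 100, 100). The
#'   symmetric ok set makes a pure partially-correct frame defuzzify to
#'   exactly 50.
#'
#' @param rig the [stereo_rig()] used to calibrate the IOU anchors.
#' @param distance_universe vertical-pixel universe `c(lo, hi)`.
#' @param distance_anchors list with elements `right` and `left`, each a
#'   named vector of membership-peak pixels, strictly increasing from
#'   `too_far` to `too_close` (a closer object sits lower in the frame).
#' @param iou_anchors named IOU percentages per class; must increase strictly
#'   from `too_close` to `too_far` (overlap grows with distance). Default:
#'   calibrated from `rig`.
#' @param iou_sigmas named Gaussian widths (IOU %); default derived from the
#'   anchor spacing as above.
#' @param output_sets list of `c(a, b, c)` triangle parameters for `low`,
#'   `ok`, `high` on \[0, 100\].
#' @param nms_threshold per-camera non-maximum-suppression IOU threshold.
#' @param resolution centroid-defuzzification grid spacing on the output
#'   universe.
#' @return an object of class `camfuse_config`.
#' @export
camfuse_config <- function(rig = default_stereo_rig(),
                           distance_universe = c(0, 720),
                           distance_anchors = NULL,
                           iou_anchors = NULL,
                           iou_sigmas = NULL,
                           output_sets = list(low = c(0, 0, 30),
                                              ok = c(30, 50, 70),
                                              high = c(70, 100, 100)),
                           nms_threshold = 0.5,
                           resolution = 0.1) {
  classes <- c("too_far", "far", "close", "too_close")
  if (is.null(distance_anchors)) {
    peaks <- c(too_far = 150, far = 300, close = 450, too_close = 600)
    distance_anchors <- list(right = peaks, left = peaks)
  }
  if (is.null(iou_anchors)) iou_anchors <- calibrate_iou_anchors(rig)
  iou_anchors <- iou_anchors[classes]
  if (is.null(iou_sigmas)) {
    ord <- iou_anchors[c("too_close", "close", "far", "too_far")]
    gaps <- diff(ord)
    nearest <- c(gaps[1], pmin(gaps[-length(gaps)], gaps[-1]), gaps[length(gaps)])
    sig <- nearest / (2 * sqrt(2 * log(2)))
    iou_sigmas <- stats::setNames(sig[match(classes, names(ord))], classes)
  }
  cfg <- structure(list(
    distance_universe = as.numeric(distance_universe),
    distance_anchors = distance_anchors,
    iou_universe = c(0, 100),
    iou_anchors = iou_anchors,
    iou_sigmas = iou_sigmas[classes],
    output_universe = c(0, 100),
    output_sets = output_sets,
    nms_threshold = nms_threshold,
    resolution = resolution
  ), class = "camfuse_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  classes <- c("too_far", "far", "close", "too_close")
  for (side in c("right", "left")) {
    a <- cfg$distance_anchors[[side]][classes]
    if (anyNA(a) || any(diff(a) <= 0)) {
      stop(sprintf("%s-camera distance anchors must increase strictly from too_far to too_close",
                   side), call. = FALSE)
    }
    if (any(a < cfg$distance_universe[1]) || any(a > cfg$distance_universe[2])) {
      stop("distance anchors must lie inside the distance universe", call. = FALSE)
    }
  }
  v <- cfg$iou_anchors[c("too_close", "close", "far", "too_far")]
  if (anyNA(v) || any(diff(v) <= 0)) {
    stop("IOU anchors must increase strictly from too_close to too_far", call. = FALSE)
  }
  if (any(cfg$iou_sigmas <= 0)) stop("IOU sigmas must be positive", call. = FALSE)
  if (!all(c("low", "ok", "high") %in% names(cfg$output_sets))) {
    stop("output_sets must define low, ok and high", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.camfuse_config <- function(x, ...) {
  cat("<camfuse_config>\n")
  cat(sprintf("  distance anchors (right): %s px\n",
              paste(sprintf("%s=%g", names(x$distance_anchors$right),
                            x$distance_anchors$right), collapse = ", ")))
  cat(sprintf("  IOU anchors: %s %%\n",
              paste(sprintf("%s=%.3g", names(x$iou_anchors), x$iou_anchors),
                    collapse = ", ")))
  cat(sprintf("  NMS threshold %.2f | centroid resolution %.3g\n",
              x$nms_threshold, x$resolution))
  invisible(x)
}

# Ruspini-style partition over the distance universe: plateau shoulders at
# the ends, triangular interiors with feet at the neighboring peaks
distance_sets <- function(peaks, universe) {
  p <- unname(peaks[c("too_far", "far", "close", "too_close")])
  list(
    too_far = mf_trapezoidal(universe[1], universe[1], p[1], p[2]),
    far = mf_triangular(p[1], p[2], p[3]),
    close = mf_triangular(p[2], p[3], p[4]),
    too_close = mf_trapezoidal(p[3], p[4], universe[2], universe[2])
  )
}

#' Build the 20-rule Mamdani confidence system
#'
#' Constructs the three input variables (right-camera box position,
#' left-camera box position, reprojected IOU overlap), the confidence output,
#' and the full rule base: four matched-anchor rules concluding High
#' (R1-R4), twelve position-mismatch rules concluding Low (R5-R16, which use
#' only the two box-position antecedents), and four negated-overlap rules
#' concluding OK (R17-R20, "IOU overlap is Not <class>").
#'
#' @param config a [camfuse_config()].
#' @return a [rule_base()].
#' @examples
#' rb <- build_confidence_system(camfuse_config())
#' length(rb$rules)  # 20
#' @export
build_confidence_system <- function(config = camfuse_config()) {
  validate_config(config)
  right <- linguistic_variable("RightCam BB", config$distance_universe,
                               distance_sets(config$distance_anchors$right,
                                             config$distance_universe),
                               units = "px")
  left <- linguistic_variable("LeftCam BB", config$distance_universe,
                              distance_sets(config$distance_anchors$left,
                                            config$distance_universe),
                              units = "px")
  classes <- c("too_far", "far", "close", "too_close")
  iou_sets <- stats::setNames(lapply(classes, function(cl) {
    mf_gaussian(config$iou_anchors[[cl]], config$iou_sigmas[[cl]])
  }), classes)
  overlap <- linguistic_variable("IOU overlap", config$iou_universe, iou_sets,
                                 units = "%")
  out_sets <- lapply(config$output_sets[c("low", "ok", "high")], function(p) {
    mf_triangular(p[1], p[2], p[3])
  })
  confidence <- linguistic_variable("Confidence", config$output_universe,
                                    out_sets, units = "%")

  rules <- list()
  # R1-R4: all three inputs at the same matched class -> High
  for (i in seq_along(classes)) {
    cl <- classes[i]
    rules[[length(rules) + 1L]] <- fuzzy_rule(
      list(list(var = "RightCam BB", is = cl),
           list(var = "IOU overlap", is = cl),
           list(var = "LeftCam BB", is = cl)),
      list(var = "Confidence", is = "high"),
      id = sprintf("R%d", i))
  }
  # R5-R16: the twelve cross-class position mismatches -> Low
  mismatch <- list(
    c("too_far", "too_close"), c("too_far", "close"), c("too_far", "far"),
    c("far", "too_far"), c("far", "close"), c("far", "too_close"),
    c("close", "too_far"), c("close", "far"), c("close", "too_close"),
    c("too_close", "close"), c("too_close", "far"), c("too_close", "too_far")
  )
  for (i in seq_along(mismatch)) {
    m <- mismatch[[i]]
    rules[[length(rules) + 1L]] <- fuzzy_rule(
      list(list(var = "RightCam BB", is = m[1]),
           list(var = "LeftCam BB", is = m[2])),
      list(var = "Confidence", is = "low"),
      id = sprintf("R%d", i + 4L))
  }
  # R17-R20: matched positions but overlap away from its anchor -> OK
  for (i in seq_along(classes)) {
    cl <- classes[i]
    rules[[length(rules) + 1L]] <- fuzzy_rule(
      list(list(var = "RightCam BB", is = cl),
           list(var = "IOU overlap", is = cl, not = TRUE),
           list(var = "LeftCam BB", is = cl)),
      list(var = "Confidence", is = "ok"),
      id = sprintf("R%d", i + 16L))
  }
  rule_base(rules, list(right, left, overlap), confidence)
}

#' Score one two-camera frame
#'
#' The end-to-end fusion pipeline: non-maximum suppression per camera, the
#' left detection reprojected onto the right image plane through `h`, the
#' cross-camera pair with maximal reprojected IOU selected, and the three
#' crisp inputs — right box vertical center, left box vertical center
#' (measured on its own plane, before reprojection), and the reprojected IOU
#' in percent — pushed through the Mamdani rule base and defuzzified by
#' centroid.
#'
#' @param left_detections,right_detections a [detection()] or list of
#'   detections per camera (at least one each).
#' @param h the left-to-right [homography()].
#' @param config a [camfuse_config()].
#' @param system optionally a prebuilt [build_confidence_system()] rule base
#'   (rebuilt from `config` when omitted).
#' @return an object of class `confidence_result`: `score` (percent),
#'   `label` (`"low"`, `"ok"` or `"high"`), `iou_after_reprojection`
#'   (percent), `inputs` (the three crisp values), `input_degrees` (per
#'   variable per set), `fired_rules` (activations of rules that fired), and
#'   the selected `pair`.
#' @export
score_frame <- function(left_detections, right_detections, h,
                        config = camfuse_config(), system = NULL) {
  as_det_list <- function(x, side) {
    if (inherits(x, "detection")) x <- list(x)
    if (length(x) == 0L) {
      stop(sprintf("no detections for the %s camera", side), call. = FALSE)
    }
    lapply(x, function(d) if (inherits(d, "detection")) d else
      detection(d$box, d$label %||% "object", d$score %||% 1))
  }
  left <- nms(as_det_list(left_detections, "left"), config$nms_threshold)
  right <- nms(as_det_list(right_detections, "right"), config$nms_threshold)

  best <- NULL
  for (l in left) {
    proj <- project_box(h, l$box)
    for (r in right) {
      v <- iou(proj, r$box)
      if (is.null(best) || v > best$iou) {
        best <- list(left = l, right = r, projected_left = proj, iou = v)
      }
    }
  }

  if (is.null(system)) system <- build_confidence_system(config)
  crisp <- list("RightCam BB" = vertical_center(best$right$box),
                "LeftCam BB" = vertical_center(best$left$box),
                "IOU overlap" = 100 * best$iou)
  agg <- aggregate_rules(system, crisp)
  degrees <- lapply(system$inputs, function(v) {
    x <- min(max(crisp[[v$name]], v$universe[1]), v$universe[2])
    vapply(v$sets, membership_degree, numeric(1), x = x)
  })
  score <- tryCatch(
    defuzzify_centroid(agg, config$resolution),
    error = function(e) {
      stop(sprintf(
        "no rule fired for inputs right=%.1f px, left=%.1f px, IOU=%.2f%%",
        crisp[["RightCam BB"]], crisp[["LeftCam BB"]], crisp[["IOU overlap"]]),
        call. = FALSE)
    })
  structure(list(
    score = score,
    label = classify_score(score, config),
    iou_after_reprojection = 100 * best$iou,
    inputs = crisp,
    input_degrees = degrees,
    fired_rules = agg$activations[agg$activations > 0],
    pair = best
  ), class = "confidence_result")
}

#' @export
print.confidence_result <- function(x, ...) {
  cat(sprintf("<confidence_result> score %.1f%% (%s) | reprojected IOU %.1f%%\n",
              x$score, x$label, x$iou_after_reprojection))
  fr <- x$fired_rules
  cat(sprintf("  fired: %s\n",
              paste(sprintf("%s=%.3g", names(fr), fr), collapse = ", ")))
  invisible(x)
}

#' Label a confidence score
#'
#' Returns the output set (`low`, `ok`, `high`) with the greatest membership
#' at `score`; ties break toward the higher-confidence label.
#'
#' @param score confidence percentage in \[0, 100\].
#' @param config a [camfuse_config()] supplying the output sets.
#' @return `"low"`, `"ok"` or `"high"`.
#' @export
classify_score <- function(score, config = camfuse_config()) {
  if (!is.finite(score) || score < 0 || score > 100) {
    stop("score must lie in [0, 100]", call. = FALSE)
  }
  labels <- c("low", "ok", "high")
  degs <- vapply(labels, function(l) {
    p <- config$output_sets[[l]]
    membership_degree(mf_triangular(p[1], p[2], p[3]), score)
  }, numeric(1))
  labels[max(which(degs == max(degs)))]
}
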