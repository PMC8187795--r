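#' Axis-aligned bounding box
#'
#' Boxes are continuous pixel regions in image coordinates (origin top-left,
#' y downward), stored in corner form. Center/size form is accepted by
#' [box_from_center()].
#'
#' @param x_min,y_min,x_max,y_max corner coordinates in pixels, with
#'   `x_max >= x_min` and `y_max >= y_min`.
#' @return an object of class `bounding_box`.
#' @examples
#' bounding_box(0, 100, 500, 450)
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max) {
  v <- as.numeric(c(x_min, y_min, x_max, y_max))
  if (length(v) != 4 || !all(is.finite(v))) {
    stop("bounding_box requires four finite coordinates", call. = FALSE)
  }
  if (v[3] < v[1] || v[4] < v[2]) {
    stop("bounding_box requires x_max >= x_min and y_max >= y_min", call. = FALSE)
  }
  structure(list(x_min = v[1], y_min = v[2], x_max = v[3], y_max = v[4]),
            class = "bounding_box")
}

#' @rdname bounding_box
#' @param cx,cy box center in pixels.
#' @param width,height box size in pixels (non-negative).
#' @export
box_from_center <- function(cx, cy, width, height) {
  if (width < 0 || height < 0) stop("box size must be non-negative", call. = FALSE)
  bounding_box(cx - width / 2, cy - height / 2, cx + width / 2, cy + height / 2)
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> [%g, %g] x [%g, %g] (%g x %g px)\n",
              x$x_min, x$x_max, x$y_min, x$y_max,
              x$x_max - x$x_min, x$y_max - x$y_min))
  invisible(x)
}

as_bounding_box <- function(b) {
  if (inherits(b, "bounding_box")) return(b)
  if (is.list(b) && all(c("x_min", "y_min", "x_max", "y_max") %in% names(b))) {
    return(bounding_box(b$x_min, b$y_min, b$x_max, b$y_max))
  }
  if (is.list(b) && all(c("cx", "cy", "width", "height") %in% names(b))) {
    return(box_from_center(b$cx, b$cy, b$width, b$height))
  }
  if (is.numeric(b) && length(b) == 4) return(bounding_box(b[1], b[2], b[3], b[4]))
  stop("cannot interpret object as a bounding box", call. = FALSE)
}

#' A labelled, scored detector output
#'
#' @param box a [bounding_box()] (or anything [bounding_box()] accepts).
#' @param label object class name (e.g. `"cocklebur"`, `"pigweed"`,
#'   `"ragweed"`).
#' @param score detector accuracy fraction in \[0, 1\].
#' @return an object of class `detection`.
#' @export
detection <- function(box, label = "object", score = 1) {
  score <- as.numeric(score)
  if (!is.finite(score) || score < 0 || score > 1) {
    stop("detection score must lie in [0, 1]", call. = FALSE)
  }
  structure(list(box = as_bounding_box(box), label = as.character(label),
                 score = score),
            class = "detection")
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("<detection> %s (score %.3f) ", x$label, x$score))
  print(x$box)
  invisible(x)
}

#' Intersection over union of two boxes
#'
#' The ratio of the overlap area to the union area, a symmetric overlap
#' fraction in \[0, 1\]: 1 for identical boxes, 0 for disjoint boxes. Boxes
#' touching only along an edge (zero intersection area) have IOU 0, and a
#' union of zero area (two degenerate boxes) is defined to give 0 rather than
#' a division by zero.
#'
#' @param a,b [bounding_box()] objects.
#' @return overlap fraction in \[0, 1\].
#' @examples
#' iou(bounding_box(0, 0, 10, 10), bounding_box(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  a <- as_bounding_box(a); b <- as_bounding_box(b)
  iw <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  ih <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  area <- function(z) (z$x_max - z$x_min) * (z$y_max - z$y_min)
  un <- area(a) + area(b) - inter
  if (un <= 0) return(0)
  inter / un
}

#' Non-maximum suppression
#'
#' Greedy SSD-style suppression: detections are visited in descending score
#' order; each kept detection discards every remaining detection whose IOU
#' with it exceeds `iou_threshold`. Any two surviving boxes therefore overlap
#' by at most `iou_threshold`, and the output is ordered by descending score.
#' Score ties are broken deterministically by smaller `x_min`, then smaller
#' `y_min`.
#'
#' @param detections a list of [detection()] objects.
#' @param iou_threshold suppression threshold in \[0, 1\] (default 0.5).
#' @return the surviving detections, descending by score.
#' @export
nms <- function(detections, iou_threshold = 0.5) {
  if (iou_threshold < 0 || iou_threshold > 1) {
    stop("iou_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (length(detections) == 0L) return(list())
  detections <- lapply(detections, function(d) {
    if (inherits(d, "detection")) d else detection(d$box, d$label %||% "object", d$score %||% 1)
  })
  sc <- vapply(detections, function(d) d$score, numeric(1))
  xm <- vapply(detections, function(d) d$box$x_min, numeric(1))
  ym <- vapply(detections, function(d) d$box$y_min, numeric(1))
  ord <- order(-sc, xm, ym)
  keep <- integer(0)
  alive <- rep(TRUE, length(ord))
  for (i in seq_along(ord)) {
    if (!alive[i]) next
    keep <- c(keep, ord[i])
    if (i < length(ord)) {
      for (j in seq(i + 1L, length(ord))) {
        if (alive[j] &&
            iou(detections[[ord[i]]]$box, detections[[ord[j]]]$box) > iou_threshold) {
          alive[j] <- FALSE
        }
      }
    }
  }
  detections[keep]
}

#' Vertical center of a box
#'
#' The fuzzy distance variables measure how far down the image a detection
#' sits: the vertical pixel distance from the top of the camera view to the
#' box center, `(y_min + y_max) / 2`.
#'
#' @param b a [bounding_box()].
#' @return the vertical center in pixels.
#' @examples
#' vertical_center(bounding_box(0, 100, 500, 450))  # 275
#' @export
vertical_center <- function(b) {
  b <- as_bounding_box(b)
  (b$y_min + b$y_max) / 2
}
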