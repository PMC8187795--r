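#' Planar homography between two image planes
#'
#' A homography is a non-singular 3x3 matrix `H` mapping homogeneous image
#' coordinates of one camera plane onto another. Only the ratios of its nine
#' entries matter (eight degrees of freedom); `homography()` therefore stores
#' the matrix normalized so that `h[3, 3] == 1`. Should the bottom-right entry
#' be numerically zero (|h33| < 1e-12), the matrix is instead scaled to unit
#' Frobenius norm and flagged with the attribute `frobenius_normalized`.
#'
#' Pixel coordinates follow the usual image convention: origin at the top-left
#' corner, x to the right, y downward, continuous (not snapped to integers).
#'
#' @param h numeric 3x3 matrix, all entries finite.
#' @return an object of class `homography`: the normalized 3x3 matrix.
#' @examples
#' homography(diag(3))
#' @export
homography <- function(h) {
  h <- as.matrix(h)
  if (!is.numeric(h) || !identical(dim(h), c(3L, 3L))) {
    stop("homography requires a numeric 3x3 matrix", call. = FALSE)
  }
  if (!all(is.finite(h))) stop("homography entries must be finite", call. = FALSE)
  # rank check on the raw matrix (scale-free)
  sv <- svd(h, nu = 0, nv = 0)$d
  if (sv[3] <= .Machine$double.eps * 100 * sv[1]) {
    stop("homography matrix is singular", call. = FALSE)
  }
  if (abs(h[3, 3]) >= 1e-12 * max(abs(h))) {
    h <- h / h[3, 3]
    frob <- FALSE
  } else {
    h <- h / sqrt(sum(h^2))
    frob <- TRUE
  }
  structure(h, class = "homography", frobenius_normalized = frob)
}

#' @export
print.homography <- function(x, ...) {
  cat("<homography> 3x3 projective map",
      if (isTRUE(attr(x, "frobenius_normalized"))) "(unit Frobenius norm)" else "(h33 = 1)",
      "\n")
  print(unclass(x)[1:3, 1:3], ...)
  invisible(x)
}

#' Test for homography objects
#' @param x object to test.
#' @return `TRUE` for objects created by [homography()].
#' @export
is_homography <- function(x) inherits(x, "homography")

as_h_matrix <- function(h) {
  if (is_homography(h)) return(matrix(as.numeric(h), 3, 3))
  homography(h)
  matrix(as.numeric(h), 3, 3)
}

#' Map image points through a homography
#'
#' Applies the projective transformation: a point (x, y) maps to
#' (x', y') with x' = (h11 x + h12 y + h13) / w and
#' y' = (h21 x + h22 y + h23) / w where w = h31 x + h32 y + h33.
#'
#' @param h a [homography()].
#' @param p a length-2 numeric `c(x, y)` or an n x 2 matrix of points (pixels).
#' @return points in the same shape as `p`.
#' @details A point whose homogeneous scale `w` vanishes maps to the plane at
#'   infinity; such degenerate projections raise an error rather than
#'   returning infinities.
#' @examples
#' project_point(homography(diag(3)), c(437, 212))
#' @export
project_point <- function(h, p) {
  m <- as_h_matrix(h)
  vec <- is.null(dim(p))
  pts <- if (vec) matrix(as.numeric(p), 1, 2) else as.matrix(p)
  if (ncol(pts) != 2 || !is.numeric(pts) || !all(is.finite(pts))) {
    stop("points must be finite (x, y) pairs", call. = FALSE)
  }
  hom <- cbind(pts, 1) %*% t(m)            # n x 3
  w <- hom[, 3]
  scale <- max(abs(m)) * (1 + rowSums(abs(pts)))
  if (any(abs(w) <= 1e-12 * scale)) {
    stop("degenerate projection: point maps to the plane at infinity", call. = FALSE)
  }
  out <- hom[, 1:2, drop = FALSE] / w
  if (vec) as.numeric(out) else out
}

#' Invert a homography
#'
#' @param h a [homography()].
#' @return the inverse map, renormalized (`invert_homography(h)` composed with
#'   `h` is the identity up to floating-point error).
#' @export
invert_homography <- function(h) {
  homography(solve(as_h_matrix(h)))
}

#' @export
solve.homography <- function(a, b, ...) {
  if (!missing(b)) return(solve(as_h_matrix(a), b, ...))
  invert_homography(a)
}

#' Compose two homographies
#'
#' `compose_homography(h2, h1)` is the map applying `h1` first, then `h2`.
#'
#' @param h2,h1 [homography()] objects.
#' @return the composite [homography()].
#' @export
compose_homography <- function(h2, h1) {
  homography(as_h_matrix(h2) %*% as_h_matrix(h1))
}

#' Mean reprojection error of a homography over correspondences
#'
#' The transfer residual of a correspondence is the Euclidean pixel distance
#' between the source point mapped through `h` and the measured target point.
#' The reported error is the mean residual in pixels per point, the unit used
#' when comparing estimation methods.
#'
#' @param h a [homography()].
#' @param correspondences a data frame with columns `x1, y1` (source plane)
#'   and `x2, y2` (target plane); see [correspondences()].
#' @return mean Euclidean deviation per point, in pixels (>= 0).
#' @export
reprojection_error <- function(h, correspondences) {
  cs <- as_correspondences(correspondences)
  if (nrow(cs) == 0L) stop("at least one correspondence is required", call. = FALSE)
  mean(transfer_distances(as_h_matrix(h), cs))
}

# Euclidean transfer distances, one per correspondence (no degeneracy guard:
# used inside estimators where wild candidate maps are expected)
transfer_distances <- function(m, cs) {
  hom <- cbind(cs$x1, cs$y1, 1) %*% t(m)
  w <- hom[, 3]
  w[w == 0] <- .Machine$double.xmin
  dx <- hom[, 1] / w - cs$x2
  dy <- hom[, 2] / w - cs$y2
  sqrt(dx * dx + dy * dy)
}

#' Construct a correspondence table
#'
#' Point correspondences pair pixel locations of the same world point on the
#' two image planes: `(x1, y1)` on the source (left, camera-2) plane and
#' `(x2, y2)` on the target (right, camera-1) plane.
#'
#' @param x1,y1 source-plane pixel coordinates.
#' @param x2,y2 target-plane pixel coordinates.
#' @return a data frame of class `correspondences`.
#' @export
correspondences <- function(x1, y1, x2, y2) {
  df <- data.frame(x1 = as.numeric(x1), y1 = as.numeric(y1),
                   x2 = as.numeric(x2), y2 = as.numeric(y2))
  if (!all(vapply(df, function(c) all(is.finite(c)), logical(1)))) {
    stop("correspondence coordinates must be finite", call. = FALSE)
  }
  class(df) <- c("correspondences", "data.frame")
  df
}

as_correspondences <- function(x) {
  if (inherits(x, "correspondences")) return(x)
  need <- c("x1", "y1", "x2", "y2")
  if (is.data.frame(x) && all(need %in% names(x))) {
    return(correspondences(x$x1, x$y1, x$x2, x$y2))
  }
  if (is.matrix(x) && ncol(x) == 4) {
    return(correspondences(x[, 1], x[, 2], x[, 3], x[, 4]))
  }
  stop("correspondences must have columns x1, y1, x2, y2", call. = FALSE)
}

#' Reproject a bounding box through a homography
#'
#' The four corners of the box are mapped individually with [project_point()];
#' a projected rectangle is in general a quadrilateral, so the axis-aligned
#' hull (bounding box) of the four mapped corners is returned. Overlap in this
#' package is always measured between axis-aligned boxes.
#'
#' @param h a [homography()].
#' @param b a [bounding_box()].
#' @return the axis-aligned [bounding_box()] of the projected corners.
#' @export
project_box <- function(h, b) {
  b <- as_bounding_box(b)
  corners <- rbind(c(b$x_min, b$y_min), c(b$x_max, b$y_min),
                   c(b$x_min, b$y_max), c(b$x_max, b$y_max))
  pc <- project_point(h, corners)
  bounding_box(min(pc[, 1]), min(pc[, 2]), max(pc[, 1]), max(pc[, 2]))
}
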