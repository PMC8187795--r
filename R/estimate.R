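#' Estimate a homography from point correspondences
#'
#' Solves for the 3x3 projective map taking source-plane points onto
#' target-plane points. Four correspondences create eight linear equations and
#' suffice for an exact solution provided no three of them are collinear; with
#' more points the map is estimated by minimizing the chosen criterion:
#'
#' * `least_mean_square` — direct linear transform (DLT) followed by a
#'   nonlinear refinement of the mean squared Euclidean transfer distance over
#'   all correspondences.
#' * `ransac` — iterative consensus: random minimal samples are fitted and the
#'   candidate with the largest inlier set (transfer distance below
#'   `params$threshold`) wins; the final map is a least-mean-square fit on the
#'   consensus inliers. Requires `params$seed`.
#' * `least_median_square` — minimizes the median squared transfer distance,
#'   searched over minimal samples (exhaustively when feasible, otherwise a
#'   seeded random subset) and polished with a direct search; robust to up to
#'   half the points being outliers.
#'
#' The DLT is conditioned with Hartley-style isotropic normalization: each
#' point set is translated to its centroid and scaled to mean distance
#' `sqrt(2)` before solving, and the solution denormalized afterwards.
#'
#' @param correspondences a [correspondences()] table (columns `x1, y1, x2,
#'   y2`) with at least four rows.
#' @param method one of `"least_mean_square"`, `"ransac"`,
#'   `"least_median_square"`.
#' @param params a list of method parameters. RANSAC: `iterations` (default
#'   2000), `threshold` (inlier transfer distance in pixels, default 3),
#'   `seed` (required). Least median of squares: `samples` (random minimal
#'   samples when exhaustive enumeration is too large, default 1500), `seed`
#'   (default 1).
#' @return an object of class `homography_fit`: a list with elements
#'   `homography`, `reprojection_error` (mean Euclidean pixels per point over
#'   the flagged inliers — all points for `least_mean_square`), `method`, and
#'   logical `inlier_flags` (one per correspondence).
#' @examples
#' h <- homography(rbind(c(1, 0, 10), c(0, 1, -5), c(0, 0, 1)))
#' src <- cbind(c(0, 100, 0, 100), c(0, 0, 80, 80))
#' dst <- project_point(h, src)
#' cs <- correspondences(src[, 1], src[, 2], dst[, 1], dst[, 2])
#' fit <- estimate_homography(cs, "least_mean_square")
#' fit$reprojection_error
#' @export
estimate_homography <- function(correspondences,
                                method = c("least_mean_square", "ransac",
                                           "least_median_square"),
                                params = list()) {
  cs <- as_correspondences(correspondences)
  method <- match.arg(method)
  n <- nrow(cs)
  if (n < 4L) stop("at least 4 correspondences are required", call. = FALSE)

  fit <- switch(method,
    least_mean_square = fit_lms(cs),
    ransac = fit_ransac(cs, params),
    least_median_square = fit_lmeds(cs, params)
  )
  err <- mean(transfer_distances(as_h_matrix(fit$h), cs)[fit$inliers])
  structure(list(homography = fit$h,
                 reprojection_error = err,
                 method = method,
                 inlier_flags = fit$inliers),
            class = "homography_fit")
}

#' @export
print.homography_fit <- function(x, ...) {
  cat(sprintf("<homography_fit> method: %s | reprojection error: %.6g px/point | inliers: %d/%d\n",
              x$method, x$reprojection_error,
              sum(x$inlier_flags), length(x$inlier_flags)))
  print(x$homography, ...)
  invisible(x)
}

# ---- internals --------------------------------------------------------------

# similarity transform sending the point cloud to centroid 0, mean norm sqrt(2)
conditioning_transform <- function(x, y) {
  cx <- mean(x); cy <- mean(y)
  d <- mean(sqrt((x - cx)^2 + (y - cy)^2))
  s <- if (d > 0) sqrt(2) / d else 1
  rbind(c(s, 0, -s * cx), c(0, s, -s * cy), c(0, 0, 1))
}

# direct linear transform with Hartley normalization; errors on degeneracy
dlt <- function(cs) {
  t1 <- conditioning_transform(cs$x1, cs$y1)
  t2 <- conditioning_transform(cs$x2, cs$y2)
  p1 <- cbind(cs$x1, cs$y1, 1) %*% t(t1)
  p2 <- cbind(cs$x2, cs$y2, 1) %*% t(t2)
  x <- p1[, 1]; y <- p1[, 2]; xp <- p2[, 1]; yp <- p2[, 2]
  zero <- rep(0, nrow(cs))
  a <- rbind(
    cbind(x, y, 1, zero, zero, zero, -xp * x, -xp * y, -xp),
    cbind(zero, zero, zero, x, y, 1, -yp * x, -yp * y, -yp)
  )
  sv <- svd(a, nu = 0, nv = 9)
  d <- sv$d
  if (d[8] <= 1e-9 * d[1]) {
    stop("degenerate correspondence configuration (collinear points): homography is rank-deficient",
         call. = FALSE)
  }
  hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  solve(t2) %*% hn %*% t1
}

# any 3 of the 4 sample points (in either plane) collinear?
minimal_sample_ok <- function(cs) {
  tri_ok <- function(x, y) {
    idx <- utils::combn(4, 3)
    for (k in seq_len(ncol(idx))) {
      i <- idx[, k]
      area <- abs((x[i[2]] - x[i[1]]) * (y[i[3]] - y[i[1]]) -
                  (x[i[3]] - x[i[1]]) * (y[i[2]] - y[i[1]]))
      span <- max(abs(diff(range(x))), abs(diff(range(y))), 1)
      if (area <= 1e-9 * span^2) return(FALSE)
    }
    TRUE
  }
  tri_ok(cs$x1, cs$y1) && tri_ok(cs$x2, cs$y2)
}

# nonlinear polish of an 8-parameter objective (h33 fixed at 1)
refine_h <- function(h0, cs, objective) {
  if (abs(h0[3, 3]) < 1e-12 * max(abs(h0))) return(h0)  # cannot pin h33 = 1
  h0 <- h0 / h0[3, 3]
  par0 <- as.numeric(t(h0))[1:8]
  fn <- function(par) {
    m <- matrix(c(par, 1), 3, 3, byrow = TRUE)
    objective(transfer_distances(m, cs))
  }
  f0 <- fn(par0)
  if (!is.finite(f0) || f0 < 1e-20) return(h0)
  opt <- stats::optim(par0, fn, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-14,
                                     parscale = pmax(abs(par0), 1e-6)))
  opt2 <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-14,
                                      parscale = pmax(abs(opt$par), 1e-6)))
  best <- if (opt2$value < opt$value) opt2 else opt
  if (best$value < f0) matrix(c(best$par, 1), 3, 3, byrow = TRUE) else h0
}

fit_lms <- function(cs) {
  h <- dlt(cs)
  h <- refine_h(h, cs, function(d) mean(d^2))
  list(h = homography(h), inliers = rep(TRUE, nrow(cs)))
}

fit_ransac <- function(cs, params) {
  iterations <- params$iterations %||% 2000L
  threshold <- params$threshold %||% 3
  if (is.null(params$seed)) {
    stop("ransac requires a seeded generator: supply params$seed", call. = FALSE)
  }
  n <- nrow(cs)
  with_local_seed(params$seed, {
    best <- NULL; best_count <- -1L; best_err <- Inf
    for (i in seq_len(iterations)) {
      idx <- sample.int(n, 4L)
      sub <- cs[idx, , drop = FALSE]
      if (!minimal_sample_ok(sub)) next
      h <- tryCatch(dlt(sub), error = function(e) NULL)
      if (is.null(h)) next
      d <- transfer_distances(h, cs)
      inl <- d < threshold
      cnt <- sum(inl)
      if (cnt > best_count ||
          (cnt == best_count && cnt > 0 && mean(d[inl]) < best_err)) {
        best <- inl; best_count <- cnt
        best_err <- if (cnt > 0) mean(d[inl]) else Inf
      }
    }
    if (is.null(best) || best_count < 4L) {
      stop("ransac failed to find a non-degenerate consensus set", call. = FALSE)
    }
    refit <- fit_lms(cs[best, , drop = FALSE])
    d <- transfer_distances(as_h_matrix(refit$h), cs)
    list(h = refit$h, inliers = d < threshold)
  })
}

fit_lmeds <- function(cs, params) {
  n <- nrow(cs)
  n_samples <- params$samples %||% 1500L
  seed <- params$seed %||% 1L
  exhaustive <- choose(n, 4) <= n_samples
  sets <- if (exhaustive) {
    utils::combn(n, 4L, simplify = FALSE)
  } else {
    with_local_seed(seed, replicate(n_samples, sample.int(n, 4L), simplify = FALSE))
  }
  best_h <- NULL; best_med <- Inf
  for (idx in sets) {
    sub <- cs[idx, , drop = FALSE]
    if (!minimal_sample_ok(sub)) next
    h <- tryCatch(dlt(sub), error = function(e) NULL)
    if (is.null(h)) next
    med <- stats::median(transfer_distances(h, cs)^2)
    if (med < best_med) { best_med <- med; best_h <- h }
  }
  if (is.null(best_h)) {
    stop("degenerate correspondence configuration (collinear points): homography is rank-deficient",
         call. = FALSE)
  }
  best_h <- refine_h(best_h, cs, function(d) stats::median(d^2))
  d2 <- transfer_distances(best_h, cs)^2
  med <- stats::median(d2)
  # robust standard deviation (Rousseeuw's finite-sample corrected scale)
  sigma <- 1.4826 * (1 + 5 / (n - 4)) * sqrt(med)
  inl <- sqrt(d2) <= max(2.5 * sigma, 1e-8)
  list(h = homography(best_h), inliers = inl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a temporarily seeded RNG, restoring global state after
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
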