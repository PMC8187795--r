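# Shared fixtures and independent oracles for the test suite.

# the published reference homography (left -> right camera plane)
ref_h_matrix <- function() {
  matrix(c(9.29968576e-01, -8.34785721e-01, 3.28368011e+02,
           3.21580417e-01, 9.89425377e-01, -3.15245367e+02,
           -7.93435882e-05, 5.73575359e-05, 1.0),
         nrow = 3, byrow = TRUE)
}

# homogeneous matrix-arithmetic oracle for point projection, coded without
# any package helpers
oracle_project <- function(m, x, y) {
  v <- m %*% c(x, y, 1)
  c(v[1] / v[3], v[2] / v[3])
}

# rectangle-overlap oracle (independent area arithmetic on corner vectors)
oracle_iou <- function(a, b) {
  # a, b: c(x_min, y_min, x_max, y_max)
  w <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  h <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- w * h
  un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  unname(if (un <= 0) 0 else inter / un)
}

# exhaustive suppression oracle: loop-based, no shared code with nms()
oracle_nms <- function(boxes, scores, threshold) {
  # boxes: n x 4 matrix; returns indices kept, in score order
  remaining <- order(-scores, boxes[, 1], boxes[, 2])
  kept <- integer(0)
  while (length(remaining) > 0) {
    i <- remaining[1]
    kept <- c(kept, i)
    remaining <- remaining[-1]
    drop <- logical(length(remaining))
    for (k in seq_along(remaining)) {
      if (oracle_iou(boxes[i, ], boxes[remaining[k], ]) > threshold) drop[k] <- TRUE
    }
    remaining <- remaining[!drop]
  }
  kept
}

# Independent dense-grid Mamdani oracle. Works straight from the numeric
# configuration (anchors, sigmas, output triangles); re-derives memberships,
# rule activations, clipping, max-aggregation and the centroid on its own
# 0.01-resolution grid.
oracle_confidence <- function(cfg, right_y, left_y, iou_pct) {
  tri <- function(x, a, b, c) {
    up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
    dn <- if (c > b) (c - x) / (c - b) else as.numeric(x <= b)
    pmax(0, pmin(up, dn, 1))
  }
  trap <- function(x, a, b, c, d) {
    up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= b)
    dn <- if (d > c) (d - x) / (d - c) else as.numeric(x <= c)
    pmax(0, pmin(up, dn, 1))
  }
  classes <- c("too_far", "far", "close", "too_close")
  dist_deg <- function(peaks, uni, x) {
    x <- min(max(x, uni[1]), uni[2])
    p <- unname(peaks[classes])
    c(too_far = trap(x, uni[1], uni[1], p[1], p[2]),
      far = tri(x, p[1], p[2], p[3]),
      close = tri(x, p[2], p[3], p[4]),
      too_close = trap(x, p[3], p[4], uni[2], uni[2]))
  }
  iou_pct <- min(max(iou_pct, cfg$iou_universe[1]), cfg$iou_universe[2])
  r <- dist_deg(cfg$distance_anchors$right, cfg$distance_universe, right_y)
  l <- dist_deg(cfg$distance_anchors$left, cfg$distance_universe, left_y)
  g <- sapply(classes, function(cl) {
    exp(-(iou_pct - cfg$iou_anchors[[cl]])^2 / (2 * cfg$iou_sigmas[[cl]]^2))
  })
  acts <- list()
  for (cl in classes) acts[[length(acts) + 1]] <- c(min(r[cl], g[cl], l[cl]), 3) # high
  mm <- list(c("too_far", "too_close"), c("too_far", "close"), c("too_far", "far"),
             c("far", "too_far"), c("far", "close"), c("far", "too_close"),
             c("close", "too_far"), c("close", "far"), c("close", "too_close"),
             c("too_close", "close"), c("too_close", "far"), c("too_close", "too_far"))
  for (m in mm) acts[[length(acts) + 1]] <- c(min(r[m[1]], l[m[2]]), 1)      # low
  for (cl in classes) acts[[length(acts) + 1]] <- c(min(r[cl], 1 - g[cl], l[cl]), 2) # ok
  x <- seq(0, 100, by = 0.01)
  outs <- list(tri(x, cfg$output_sets$low[1], cfg$output_sets$low[2], cfg$output_sets$low[3]),
               tri(x, cfg$output_sets$ok[1], cfg$output_sets$ok[2], cfg$output_sets$ok[3]),
               tri(x, cfg$output_sets$high[1], cfg$output_sets$high[2], cfg$output_sets$high[3]))
  mu <- numeric(length(x))
  for (a in acts) {
    if (a[1] > 0) mu <- pmax(mu, pmin(a[1], outs[[a[2]]]))
  }
  if (sum(mu) <= 0) return(NA_real_)
  sum(x * mu) / sum(mu)
}

random_boxes <- function(n, max_xy = 100, max_wh = 40) {
  x0 <- runif(n, 0, max_xy); y0 <- runif(n, 0, max_xy)
  cbind(x0, y0, x0 + runif(n, 1, max_wh), y0 + runif(n, 1, max_wh))
}
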