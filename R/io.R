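#' Read per-camera detections from JSON
#'
#' Expects a JSON array of records
#' `{camera, frame, label, score, box: {x_min, y_min, x_max, y_max}}`; a box
#' may equivalently be given in center form `{cx, cy, width, height}`. Scores
#' are detector accuracy fractions in \[0, 1\]; a value in (1, 100\] is taken
#' to be a percentage and divided by 100 with a warning.
#'
#' @param path JSON file path.
#' @param default_camera camera name (`"left"`/`"right"`) assumed for records
#'   without a `camera` field.
#' @return a list with elements `left` and `right`, each a list of
#'   [detection()] objects (possibly empty).
#' @export
read_detections <- function(path, default_camera = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(recs)) stop("detections file must hold a JSON array", call. = FALSE)
  out <- list(left = list(), right = list())
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    cam <- r$camera %||% default_camera
    if (is.null(cam) || !cam %in% c("left", "right")) {
      stop(sprintf("detection %d: missing or invalid 'camera' field", i), call. = FALSE)
    }
    if (is.null(r$box)) {
      stop(sprintf("detection %d: missing 'box' field", i), call. = FALSE)
    }
    box <- tryCatch(as_bounding_box(r$box), error = function(e) {
      stop(sprintf("detection %d: invalid 'box' (%s)", i, conditionMessage(e)),
           call. = FALSE)
    })
    score <- r$score %||% 1
    if (!is.numeric(score) || !is.finite(score) || score < 0 || score > 100) {
      stop(sprintf("detection %d: invalid 'score' field", i), call. = FALSE)
    }
    if (score > 1) {
      warning(sprintf("detection %d: score %g looks like a percentage; dividing by 100",
                      i, score), call. = FALSE)
      score <- score / 100
    }
    out[[cam]] <- c(out[[cam]],
                    list(detection(box, r$label %||% "object", score)))
  }
  out
}

#' Write detections to JSON
#'
#' @param path output file.
#' @param left,right lists of [detection()] objects.
#' @param frame optional frame index recorded on every record.
#' @return `path`, invisibly.
#' @export
write_detections <- function(path, left = list(), right = list(), frame = 0L) {
  rec <- function(d, cam) {
    list(camera = cam, frame = frame, label = d$label, score = d$score,
         box = list(x_min = d$box$x_min, y_min = d$box$y_min,
                    x_max = d$box$x_max, y_max = d$box$y_max))
  }
  if (inherits(left, "detection")) left <- list(left)
  if (inherits(right, "detection")) right <- list(right)
  recs <- c(lapply(left, rec, cam = "left"), lapply(right, rec, cam = "right"))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read point correspondences from CSV
#'
#' The file must carry the header `x1,y1,x2,y2` (source/left plane first,
#' target/right plane second), one correspondence per row, pixel units.
#' Surrounding whitespace is tolerated.
#'
#' @param path CSV file path.
#' @return a [correspondences()] table.
#' @export
read_correspondences <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) {
    stop("correspondence file must have a header and at least one row", call. = FALSE)
  }
  header <- tolower(gsub("[[:space:]]", "", lines[1]))
  if (header != "x1,y1,x2,y2") {
    stop("correspondence CSV must start with header 'x1,y1,x2,y2'", call. = FALSE)
  }
  rows <- lapply(seq_along(lines)[-1], function(i) {
    parts <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]])
    if (length(parts) != 4) {
      stop(sprintf("row %d: expected 4 columns, found %d", i, length(parts)),
           call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v)) stop(sprintf("row %d: non-numeric value", i), call. = FALSE)
    v
  })
  m <- do.call(rbind, rows)
  correspondences(m[, 1], m[, 2], m[, 3], m[, 4])
}

#' Write correspondences to CSV
#'
#' @param path output file.
#' @param cs a [correspondences()] table.
#' @return `path`, invisibly.
#' @export
write_correspondences <- function(path, cs) {
  cs <- as_correspondences(cs)
  lines <- c("x1,y1,x2,y2",
             sprintf("%s,%s,%s,%s",
                     format(cs$x1, digits = 17, trim = TRUE, scientific = FALSE),
                     format(cs$y1, digits = 17, trim = TRUE, scientific = FALSE),
                     format(cs$x2, digits = 17, trim = TRUE, scientific = FALSE),
                     format(cs$y2, digits = 17, trim = TRUE, scientific = FALSE)))
  writeLines(lines, path)
  invisible(path)
}

#' Homography file I/O
#'
#' A homography is stored as a JSON object with key `h` holding the 3x3
#' nested array (row-major, `h[3][3] == 1`). Numbers are written at full
#' double precision so that write/read round-trips are bit-exact. A
#' [estimate_homography()] result additionally records `method`,
#' `reprojection_error` and `inlier_flags`.
#'
#' @param path JSON file path.
#' @param x a [homography()] or `homography_fit`.
#' @return `read_homography()` returns a [homography()] (with the estimation
#'   metadata in attribute `fit` when present); `write_homography()` returns
#'   `path` invisibly.
#' @export
write_homography <- function(path, x) {
  obj <- if (inherits(x, "homography_fit")) {
    list(h = unclass(as_h_matrix(x$homography)),
         method = x$method,
         reprojection_error = x$reprojection_error,
         inlier_flags = x$inlier_flags)
  } else {
    list(h = unclass(as_h_matrix(x)))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_homography
#' @export
read_homography <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$h)) stop("homography file must hold a key 'h'", call. = FALSE)
  h <- homography(matrix(as.numeric(t(obj$h)), 3, 3, byrow = TRUE))
  if (!is.null(obj$method)) {
    attr(h, "fit") <- list(method = obj$method,
                           reprojection_error = obj$reprojection_error,
                           inlier_flags = obj$inlier_flags)
  }
  h
}

#' Configuration file I/O
#'
#' A [camfuse_config()] round-trips through YAML (default) or JSON, picked by
#' file extension.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @param config a [camfuse_config()].
#' @return `read_config()` returns the validated [camfuse_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(path, config) {
  validate_config(config)
  obj <- unclass(config)
  obj$distance_anchors <- lapply(obj$distance_anchors, as.list)
  obj$iou_anchors <- as.list(obj$iou_anchors)
  obj$iou_sigmas <- as.list(obj$iou_sigmas)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  } else {
    yaml::write_yaml(obj, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- camfuse_config(
    distance_universe = as.numeric(obj$distance_universe),
    distance_anchors = lapply(obj$distance_anchors, function(a) unlist(a)),
    iou_anchors = unlist(obj$iou_anchors),
    iou_sigmas = unlist(obj$iou_sigmas),
    output_sets = lapply(obj$output_sets, as.numeric),
    nms_threshold = as.numeric(obj$nms_threshold),
    resolution = as.numeric(obj$resolution)
  )
  cfg
}

#' Run manifest
#'
#' Every command-line run writes a small provenance record next to its
#' output: command name, input paths, a digest of the configuration, the
#' seed, the package version and a timestamp.
#'
#' @param command subcommand name.
#' @param inputs named character vector of input file paths.
#' @param config_path configuration file used (`NA` for the built-in
#'   default).
#' @param seed integer seed or `NA`.
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(command, inputs = character(), config_path = NA,
                         seed = NA) {
  digest <- if (is.character(config_path) && !is.na(config_path) &&
                file.exists(config_path)) {
    unname(tools::md5sum(config_path))
  } else {
    "default"
  }
  structure(list(
    command = command,
    inputs = as.list(inputs),
    config_digest = digest,
    seed = seed,
    version = as.character(utils::packageVersion("camfuse")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

write_manifest <- function(out_path, manifest) {
  path <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE)
  invisible(path)
}
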