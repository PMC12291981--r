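#' Read a YOLO-format label file
#'
#' One whitespace-separated record per line: `class cx cy w h` for ground
#' truth or `class cx cy w h conf` for detections, all but the class
#' normalized to \[0, 1\]. Values are denormalized against the canvas
#' using continuous coordinates (no pixel-index offsets): a record
#' `0 0.5 0.5 0.25 0.25` on a 640 x 640 canvas is the box
#' (240, 240, 400, 400).
#'
#' @param path Path to the label file.
#' @param canvas `c(width, height)` in pixels used for denormalization.
#' @return A detections data frame if the file has 6-field records, a box
#'   data frame (with a `class_id` attribute column dropped) for 5-field
#'   records, or an empty box data frame for an empty file. Mixed 5/6
#'   field files are rejected.
#' @export
read_label_file <- function(path, canvas) {
  stopifnot(length(canvas) == 2, all(canvas > 0))
  if (!file.exists(path)) stop(sprintf("label file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(boxes(numeric(0), numeric(0), numeric(0), numeric(0)))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (!all(nf %in% c(5L, 6L)) || length(unique(nf)) != 1) {
    bad <- which(!(nf %in% c(5L, 6L)) | nf != nf[1])[1]
    stop(sprintf("%s:%d: expected %s whitespace-separated fields, got %d",
                 path, bad, "5 (ground truth) or 6 (detection)", nf[bad]))
  }
  m <- matrix(NA_real_, length(fields), nf[1])
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (any(is.na(v))) {
      stop(sprintf("%s:%d: non-numeric field in record '%s'", path, i, lines[i]))
    }
    m[i, ] <- v
  }
  norm <- m[, 2:5, drop = FALSE]
  if (any(norm < 0) || any(norm > 1)) {
    bad <- which(apply(norm < 0 | norm > 1, 1, any))[1]
    stop(sprintf("%s:%d: normalized value outside [0, 1]", path, bad))
  }
  b <- boxes(
    x_min = (m[, 2] - m[, 4] / 2) * canvas[1],
    y_min = (m[, 3] - m[, 5] / 2) * canvas[2],
    x_max = (m[, 2] + m[, 4] / 2) * canvas[1],
    y_max = (m[, 3] + m[, 5] / 2) * canvas[2]
  )
  if (nf[1] == 6L) {
    conf <- m[, 6]
    if (any(conf < 0) || any(conf > 1)) {
      stop(sprintf("%s: confidence outside [0, 1]", path))
    }
    detections(b, score = conf, class_id = as.integer(m[, 1]))
  } else {
    b
  }
}

#' Write boxes or detections as a YOLO-format label file
#'
#' Normalizes against the canvas and writes fixed-point records with six
#' decimal places, one per input row in input order, newline-terminated.
#' Boxes extending past the canvas are clipped to it with a warning.
#'
#' @param items A box or detections data frame; detections (a `score`
#'   column) produce 6-field records.
#' @param path Output path.
#' @param canvas `c(width, height)` in pixels.
#' @return `path`, invisibly.
#' @export
write_label_file <- function(items, path, canvas) {
  stopifnot(length(canvas) == 2, all(canvas > 0))
  if (NROW(items) > 0) validate_boxes(items)
  b <- items
  out_of_canvas <- NROW(b) > 0 &&
    (any(b$x_min < 0) || any(b$y_min < 0) ||
     any(b$x_max > canvas[1]) || any(b$y_max > canvas[2]))
  if (out_of_canvas) {
    warning("boxes exceeding the canvas were clipped on write")
    b$x_min <- pmax(b$x_min, 0)
    b$y_min <- pmax(b$y_min, 0)
    b$x_max <- pmin(b$x_max, canvas[1])
    b$y_max <- pmin(b$y_max, canvas[2])
  }
  cls <- if ("class_id" %in% names(b)) b$class_id else rep(0L, NROW(b))
  cx <- (b$x_min + b$x_max) / 2 / canvas[1]
  cy <- (b$y_min + b$y_max) / 2 / canvas[2]
  w <- (b$x_max - b$x_min) / canvas[1]
  h <- (b$y_max - b$y_min) / canvas[2]
  lines <- if ("score" %in% names(b)) {
    sprintf("%d %.6f %.6f %.6f %.6f %.6f", cls, cx, cy, w, h, b$score)
  } else {
    sprintf("%d %.6f %.6f %.6f %.6f", cls, cx, cy, w, h)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read COCO-style detection results
#'
#' Reads a JSON array of detection records, each with `image_id`,
#' `category_id`, `bbox` (as `[x, y, width, height]`) and `score`. Boxes
#' are converted to corner convention on read.
#'
#' @param path Path to the JSON file.
#' @return A detections data frame with an extra `image_id` column; an
#'   empty detections frame for an empty array.
#' @export
read_coco_detections <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(recs) == 0) {
    d <- empty_detections()
    d$image_id <- character(0)
    return(d)
  }
  need <- c("image_id", "category_id", "bbox", "score")
  for (i in seq_along(recs)) {
    missing <- setdiff(need, names(recs[[i]]))
    if (length(missing) > 0) {
      stop(sprintf("%s: record %d is missing required key(s): %s",
                   path, i, paste(missing, collapse = ", ")))
    }
    if (length(recs[[i]]$bbox) != 4) {
      stop(sprintf("%s: record %d has a bbox that is not [x, y, w, h]", path, i))
    }
  }
  bb <- t(vapply(recs, function(r) as.numeric(r$bbox), numeric(4)))
  d <- detections(
    boxes(bb[, 1], bb[, 2], bb[, 1] + bb[, 3], bb[, 2] + bb[, 4]),
    score = vapply(recs, function(r) as.numeric(r$score), numeric(1)),
    class_id = vapply(recs, function(r) as.integer(r$category_id), integer(1))
  )
  d$image_id <- vapply(recs, function(r) as.character(r$image_id), character(1))
  d
}

#' Write detections as COCO-style detection results
#'
#' @param dets A detections data frame; an optional `image_id` column is
#'   used, otherwise `image_id` applies to all rows.
#' @param path Output path.
#' @param image_id Fallback image identifier.
#' @return `path`, invisibly.
#' @export
write_coco_detections <- function(dets, path, image_id = "image-1") {
  if (NROW(dets) > 0) validate_detections(dets)
  ids <- if ("image_id" %in% names(dets)) dets$image_id else
    rep(image_id, NROW(dets))
  recs <- lapply(seq_len(NROW(dets)), function(i) {
    list(
      image_id = ids[i],
      category_id = dets$class_id[i],
      bbox = c(dets$x_min[i], dets$y_min[i],
               dets$x_max[i] - dets$x_min[i], dets$y_max[i] - dets$y_min[i]),
      score = dets$score[i]
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a metric report
#'
#' Serializes a flat named list of metrics as JSON or aligned plain text.
#' The canonical metric names are `precision`, `recall`, `f1`, `map50`,
#' `average_accuracy`, `mae`, `rmse`; any parameters recorded alongside
#' (thresholds, seeds) are written as additional keys.
#'
#' @param metrics A named list of scalars.
#' @param path Output path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(metrics, path, format = c("json", "text")) {
  format <- match.arg(format)
  stopifnot(is.list(metrics), length(names(metrics)) == length(metrics))
  if (format == "json") {
    jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(sprintf("%-18s %s", names(metrics),
                       vapply(metrics, format_metric, character(1))), path)
  }
  invisible(path)
}

format_metric <- function(x) {
  if (is.numeric(x)) format(x, digits = 10) else as.character(x)
}
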