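#' Construct a set of axis-aligned bounding boxes
#'
#' Boxes live in continuous image coordinates (x to the right, y down) and
#' are stored as a data frame with one row per box and columns `x_min`,
#' `y_min`, `x_max`, `y_max`. Widths and heights are arithmetic differences
#' (`x_max - x_min`), with no pixel-index offset convention.
#'
#' @param x_min,y_min,x_max,y_max Numeric vectors of corner coordinates,
#'   recycled to a common length. Every box must have strictly positive
#'   width and height and finite coordinates.
#'
#' @return A data frame of class `dc_boxes` with columns `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @examples
#' boxes(0, 0, c(2, 3), c(2, 2))
#' @export
boxes <- function(x_min, y_min, x_max, y_max) {
  b <- data.frame(
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max)
  )
  validate_boxes(b)
  class(b) <- c("dc_boxes", "data.frame")
  b
}

#' Validate box geometry
#'
#' Checks the box invariants: finite coordinates and strictly positive
#' area. Degenerate (zero- or negative-area) boxes are rejected because
#' every downstream score (IoU, PIoU) divides by box dimensions.
#'
#' @param b A data frame with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @return `b`, invisibly, if valid; otherwise an error of class
#'   `densecount_invalid_geometry`.
#' @export
validate_boxes <- function(b) {
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (!is.data.frame(b) || !all(need %in% names(b))) {
    stop_invalid_geometry("boxes must be a data frame with columns x_min, y_min, x_max, y_max")
  }
  m <- as.matrix(b[need])
  if (!all(is.finite(m))) {
    stop_invalid_geometry("box coordinates must all be finite")
  }
  if (any(b$x_max <= b$x_min) || any(b$y_max <= b$y_min)) {
    bad <- which(b$x_max <= b$x_min | b$y_max <= b$y_min)[1]
    stop_invalid_geometry(sprintf(
      "degenerate box at row %d: width and height must be strictly positive", bad
    ))
  }
  invisible(b)
}

stop_invalid_geometry <- function(msg) {
  stop(errorCondition(msg, class = c("densecount_invalid_geometry", "error")))
}

#' @rdname box_geometry
#' @export
box_width <- function(b) b$x_max - b$x_min

#' @rdname box_geometry
#' @export
box_height <- function(b) b$y_max - b$y_min

#' Box derived geometry
#'
#' Width, height, area and center of each box.
#'
#' @param b A box data frame (see [boxes()]).
#' @return `box_width()`, `box_height()` and `box_area()` return numeric
#'   vectors; `box_center()` a two-column matrix (`cx`, `cy`).
#' @name box_geometry
#' @export
box_area <- function(b) (b$x_max - b$x_min) * (b$y_max - b$y_min)

#' @rdname box_geometry
#' @export
box_center <- function(b) {
  cbind(cx = (b$x_min + b$x_max) / 2, cy = (b$y_min + b$y_max) / 2)
}

#' Construct a set of detections
#'
#' A detection is a box plus a confidence score and an integer class label.
#' This toolkit is single-class (class 0 = pig) and all suppression is
#' class-agnostic, but the label is carried through for interoperability
#' with label-file formats.
#'
#' @param box A box data frame (see [boxes()]).
#' @param score Confidence scores in \[0, 1\], one per box.
#' @param class_id Integer class labels, recycled (default 0).
#' @return A data frame of class `dc_detections` with the box columns plus
#'   `score` and `class_id`.
#' @examples
#' detections(boxes(0, 0, 2, 2), score = 0.9)
#' @export
detections <- function(box, score, class_id = 0L) {
  validate_boxes(box)
  score <- as.numeric(score)
  if (length(score) != nrow(box)) {
    stop("`score` must have one value per box")
  }
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1)) {
    stop("confidence scores must be finite and in [0, 1]")
  }
  d <- data.frame(
    x_min = box$x_min, y_min = box$y_min,
    x_max = box$x_max, y_max = box$y_max,
    score = score,
    class_id = as.integer(rep_len(class_id, nrow(box)))
  )
  class(d) <- c("dc_detections", "data.frame")
  d
}

as_boxes <- function(d) {
  boxes(d$x_min, d$y_min, d$x_max, d$y_max)
}
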