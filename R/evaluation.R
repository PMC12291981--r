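#' Match detections to ground-truth boxes
#'
#' Greedy matching by descending confidence: each detection claims the
#' still-unmatched ground-truth box with which it has the highest IoU; it
#' is a true positive if that IoU is at least `iou_threshold` (the box
#' then becomes matched), otherwise a false positive. Ground-truth boxes
#' left unmatched are false negatives. Ties in confidence are broken by
#' detection input order and ties in IoU by ground-truth index, so the
#' matching is deterministic.
#'
#' @param dets A detections data frame (may be empty).
#' @param gts A box data frame of ground-truth boxes.
#' @param iou_threshold Minimum IoU for a true positive; default 0.5.
#' @return A list of class `match_result` with integer fields `tp`, `fp`,
#'   `fn` and a logical vector `is_tp` of per-detection flags ordered by
#'   descending confidence (the order also returned in `det_order`).
#'   Always satisfies `tp + fn == nrow(gts)` and `tp + fp == nrow(dets)`.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  stopifnot(is.numeric(iou_threshold), length(iou_threshold) == 1,
            iou_threshold > 0, iou_threshold <= 1)
  n_gt <- NROW(gts)
  if (n_gt > 0) validate_boxes(gts)
  if (NROW(dets) == 0) {
    return(structure(list(tp = 0L, fp = 0L, fn = as.integer(n_gt),
                          is_tp = logical(0), det_order = integer(0)),
                     class = "match_result"))
  }
  validate_detections(dets)
  ord <- order(-dets$score, seq_len(nrow(dets)))
  d <- dets[ord, , drop = FALSE]
  is_tp <- logical(nrow(d))
  if (n_gt > 0) {
    m <- box_iou_matrix(as_boxes(d), gts)
    matched <- logical(n_gt)
    for (i in seq_len(nrow(d))) {
      avail <- which(!matched)
      if (length(avail) == 0) break
      j <- avail[which.max(m[i, avail])]
      if (m[i, j] >= iou_threshold) {
        is_tp[i] <- TRUE
        matched[j] <- TRUE
      }
    }
  }
  tp <- sum(is_tp)
  structure(list(tp = as.integer(tp),
                 fp = as.integer(nrow(d) - tp),
                 fn = as.integer(n_gt - tp),
                 is_tp = is_tp, det_order = ord),
            class = "match_result")
}

#' Precision, recall and F1 from a matching
#'
#' Precision = TP / (TP + FP), recall = TP / (TP + FN), and F1 their
#' harmonic mean. A metric whose denominator is zero is undefined and
#' reported as `NA` with the corresponding `defined_*` flag set to
#' `FALSE`, never silently coerced to 0; the sole exception is F1 when
#' precision and recall are both defined and both 0, which is reported
#' as 0 (the limiting value) with a flag.
#'
#' @param match A `match_result` (see [match_detections()]) or any list
#'   with integer `tp`, `fp`, `fn`.
#' @return A list with `precision`, `recall`, `f1` (each in \[0, 1\] or
#'   `NA`) and logical flags `defined_precision`, `defined_recall`,
#'   `defined_f1`.
#' @export
precision_recall_f1 <- function(match) {
  tp <- match$tp
  fp <- match$fp
  fn <- match$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  defined_p <- (tp + fp) > 0
  defined_r <- (tp + fn) > 0
  p <- if (defined_p) tp / (tp + fp) else NA_real_
  r <- if (defined_r) tp / (tp + fn) else NA_real_
  defined_f <- defined_p && defined_r
  f1 <- if (!defined_f) {
    NA_real_
  } else if (p + r == 0) {
    0 # limiting value when precision = recall = 0
  } else {
    2 * p * r / (p + r)
  }
  list(precision = p, recall = r, f1 = f1,
       defined_precision = defined_p, defined_recall = defined_r,
       defined_f1 = defined_f && (p + r) > 0)
}

#' Precision-recall curve and average precision
#'
#' Ranks detections by descending confidence, accumulates true and false
#' positives against the greedy matching of [match_detections()], and
#' integrates the precision envelope over recall: at each recall level the
#' precision used is the maximum precision attained at that recall or
#' higher (all-point interpolation; neither the 11-point nor the 101-point
#' approximation). For a single category, mean average precision equals
#' this AP.
#'
#' @param dets A detections data frame.
#' @param gts A box data frame of ground-truth boxes; must be non-empty
#'   (AP is undefined with no ground truth).
#' @param iou_threshold Minimum IoU for a true positive; default 0.5.
#' @return A list of class `pr_curve` with vectors `recall` and
#'   `precision` indexed by detection rank, scalar `ap`, and `n_categories
#'   = 1`.
#' @export
average_precision <- function(dets, gts, iou_threshold = 0.5) {
  if (NROW(gts) == 0) {
    stop("average precision is undefined with no ground-truth boxes")
  }
  validate_boxes(gts)
  match <- match_detections(dets, gts, iou_threshold)
  n_gt <- nrow(gts)
  if (length(match$is_tp) == 0) {
    return(structure(list(recall = numeric(0), precision = numeric(0),
                          ap = 0, n_categories = 1L),
                     class = "pr_curve"))
  }
  cum_tp <- cumsum(match$is_tp)
  rank <- seq_along(match$is_tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / rank
  # precision envelope: max precision at this recall or any higher recall
  envelope <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * envelope)
  structure(list(recall = recall, precision = precision, ap = ap,
                 n_categories = 1L),
            class = "pr_curve")
}

#' Scene-level counting metrics
#'
#' Given per-scene pairs of true count \eqn{a_i} and predicted count
#' \eqn{b_i} over \eqn{m} scenes:
#' \deqn{\mathrm{average\_accuracy} = \frac{1}{m} \sum_i
#'   \left(1 - \frac{|a_i - b_i|}{a_i}\right), \quad
#'   \mathrm{MAE} = \frac{1}{m} \sum_i |a_i - b_i|, \quad
#'   \mathrm{RMSE} = \sqrt{\frac{1}{m} \sum_i (a_i - b_i)^2}.}
#' Average accuracy is 1 exactly when every count is exact and can be
#' negative when an error exceeds the true count. Scenes with a true count
#' of zero are rejected (the relative error is undefined).
#'
#' @param pairs A data frame with columns `a` (true count, at least 1) and
#'   `b` (predicted count, non-negative); an optional `scene_id` column is
#'   carried through. See [count_pairs()].
#' @return A list of class `counting_report` with `average_accuracy`,
#'   `mae`, `rmse` and `m` (number of scenes).
#' @examples
#' counting_metrics(count_pairs(a = c(27, 10, 22), b = c(26, 10, 22)))
#' @export
counting_metrics <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("a", "b") %in% names(pairs)),
            nrow(pairs) >= 1)
  a <- pairs$a
  b <- pairs$b
  if (any(a < 1) || any(a != round(a))) {
    stop("true counts `a` must be positive integers (relative error is undefined at a = 0)")
  }
  if (any(b < 0) || any(b != round(b))) {
    stop("predicted counts `b` must be non-negative integers")
  }
  err <- abs(a - b)
  structure(list(
    average_accuracy = mean(1 - err / a),
    mae = mean(err),
    rmse = sqrt(mean((a - b)^2)),
    m = nrow(pairs)
  ), class = "counting_report")
}

#' Build scene-level count pairs
#'
#' @param a True counts (positive integers).
#' @param b Predicted counts (non-negative integers).
#' @param scene_id Optional scene identifiers.
#' @return A data frame with columns `scene_id`, `a`, `b`.
#' @export
count_pairs <- function(a, b, scene_id = seq_along(a)) {
  stopifnot(length(a) == length(b))
  data.frame(scene_id = scene_id, a = as.integer(a), b = as.integer(b))
}

#' @export
print.counting_report <- function(x, ...) {
  cat(sprintf("counting over %d scenes: average_accuracy %.4f, MAE %.3f, RMSE %.3f\n",
              x$m, x$average_accuracy, x$mae, x$rmse))
  invisible(x)
}
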