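#' Detection metrics for one scene
#'
#' Convenience wrapper combining [match_detections()],
#' [precision_recall_f1()] and [average_precision()] into the flat report
#' used by the report writers: `precision`, `recall`, `f1`, `map50` (AP
#' at the given IoU threshold; mean AP over the single class).
#'
#' @param dets A detections data frame.
#' @param gts A box data frame of ground-truth boxes (non-empty).
#' @param iou_threshold True-positive IoU threshold; default 0.5.
#' @return A named list with `precision`, `recall`, `f1`, `map50`,
#'   `tp`, `fp`, `fn`, and `iou_threshold`.
#' @export
evaluate_detections <- function(dets, gts, iou_threshold = 0.5) {
  match <- match_detections(dets, gts, iou_threshold)
  prf <- precision_recall_f1(match)
  pr <- average_precision(dets, gts, iou_threshold)
  list(precision = prf$precision, recall = prf$recall, f1 = prf$f1,
       map50 = pr$ap, tp = match$tp, fp = match$fp, fn = match$fn,
       iou_threshold = iou_threshold)
}

#' Run the density-aware counting pipeline over a batch of scenes
#'
#' Applies [density_aware_count()] to each scene's detections and
#' assembles the scene-level count pairs and counting report.
#'
#' @param scenes A list of `gt_scene` objects.
#' @param dets_list A list of detections data frames, parallel to
#'   `scenes`.
#' @param conf_init,soft_params Passed to [density_aware_count()].
#' @return A list with `pairs` (the [count_pairs()] data frame including
#'   a `tier` column), and `report` (the [counting_metrics()] result).
#' @export
count_scenes <- function(scenes, dets_list, conf_init = 0.25,
                         soft_params = soft_nms_params()) {
  stopifnot(length(scenes) == length(dets_list))
  res <- lapply(seq_along(scenes), function(i) {
    dc <- density_aware_count(dets_list[[i]], conf_init, soft_params)
    data.frame(scene_id = scenes[[i]]$scene_id, a = scenes[[i]]$a,
               b = dc$count, tier = dc$tier$name)
  })
  pairs <- do.call(rbind, res)
  list(pairs = pairs, report = counting_metrics(pairs))
}
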