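# Independent scalar oracles and brute-force references.
# These operate on plain numeric 4-vectors c(x_min, y_min, x_max, y_max)
# and deliberately share no code with the package implementations.

scalar_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (area_a + area_b - inter)
}

scalar_piou <- function(pred, gt, alpha = 1) {
  w <- pred[3] - pred[1]; h <- pred[4] - pred[2]
  wg <- gt[3] - gt[1]; hg <- gt[4] - gt[2]
  cx <- (pred[1] + pred[3]) / 2; cy <- (pred[2] + pred[4]) / 2
  gx <- (gt[1] + gt[3]) / 2; gy <- (gt[2] + gt[4]) / 2
  rho2 <- (cx - gx)^2 + (cy - gy)^2
  scalar_iou(pred, gt) - rho2 / (w^2 + h^2) -
    alpha * ((wg - w)^2 + (hg - h)^2) / (wg^2 + hg^2)
}

scalar_piou_v2 <- function(pred, gt, lam = 0.5, alpha = 1) {
  w <- pred[3] - pred[1]; h <- pred[4] - pred[2]
  wg <- gt[3] - gt[1]; hg <- gt[4] - gt[2]
  cx <- (pred[1] + pred[3]) / 2; cy <- (pred[2] + pred[4]) / 2
  gx <- (gt[1] + gt[3]) / 2; gy <- (gt[2] + gt[4]) / 2
  rho2 <- (cx - gx)^2 + (cy - gy)^2
  ew <- max(pred[3], gt[3]) - min(pred[1], gt[1])
  eh <- max(pred[4], gt[4]) - min(pred[2], gt[2])
  delta <- rho2 / (ew^2 + eh^2) + ((w - wg)^2 + (h - hg)^2) / (wg^2 + hg^2)
  u <- scalar_iou(pred, gt)
  phi <- 4 * u * (1 - u)
  psi <- 1 - exp(-delta)
  1 - scalar_piou(pred, gt, alpha) + lam * phi * psi
}

# O(n^2) greedy hard-NMS reference: returns the kept original row indices
# in descending-score order (ties by input index).
ref_hard_nms_idx <- function(det_mat, scores, thr) {
  ord <- order(-scores, seq_along(scores))
  kept <- integer(0)
  removed <- rep(FALSE, length(scores))
  for (i in ord) {
    if (removed[i]) next
    kept <- c(kept, i)
    for (j in ord) {
      if (!removed[j] && j != i &&
          scalar_iou(det_mat[i, ], det_mat[j, ]) > thr) {
        removed[j] <- TRUE
      }
    }
    removed[i] <- TRUE
  }
  kept
}

# Greedy matching reference: same protocol as match_detections, coded
# independently; returns c(tp, fp, fn).
ref_match_counts <- function(det_mat, scores, gt_mat, thr) {
  ord <- order(-scores, seq_along(scores))
  matched <- rep(FALSE, nrow(gt_mat))
  tp <- 0
  for (i in ord) {
    best_j <- 0; best_iou <- -1
    for (j in seq_len(nrow(gt_mat))) {
      if (matched[j]) next
      v <- scalar_iou(det_mat[i, ], gt_mat[j, ])
      if (v > best_iou) { best_iou <- v; best_j <- j }
    }
    if (best_j > 0 && best_iou >= thr) {
      tp <- tp + 1
      matched[best_j] <- TRUE
    }
  }
  c(tp = tp, fp = length(scores) - tp, fn = nrow(gt_mat) - tp)
}

# Random box generators -------------------------------------------------

random_box_mat <- function(n, field = 100, min_size = 2, max_size = 20) {
  x <- runif(n, 0, field - max_size)
  y <- runif(n, 0, field - max_size)
  w <- runif(n, min_size, max_size)
  h <- runif(n, min_size, max_size)
  cbind(x, y, x + w, y + h)
}

random_boxes <- function(n, field = 100) {
  m <- random_box_mat(n, field)
  boxes(m[, 1], m[, 2], m[, 3], m[, 4])
}

random_detections <- function(n, field = 100) {
  detections(random_boxes(n, field), score = runif(n))
}

# Boxes on a coarse integer grid: any two either have IoU 0 or an IoU of
# at least ~0.05, so Gaussian decay at sigma -> 0 is unambiguous.
grid_detections <- function(n, field = 20) {
  x <- 2 * sample.int(field / 2 - 3, n, replace = TRUE)
  y <- 2 * sample.int(field / 2 - 3, n, replace = TRUE)
  w <- 2 * sample.int(3, n, replace = TRUE)
  h <- 2 * sample.int(3, n, replace = TRUE)
  # scores bounded away from the keep floor used in the sigma -> 0 limit
  # checks, where the equivalence with hard NMS presupposes undecayed
  # scores survive the floor
  detections(boxes(x, y, x + w, y + h), score = runif(n, 0.1, 1))
}

det_mat <- function(d) {
  m <- as.matrix(d[, c("x_min", "y_min", "x_max", "y_max")])
  dimnames(m) <- NULL
  m
}

empty_dets <- function() {
  detections(boxes(numeric(0), numeric(0), numeric(0), numeric(0)),
             score = numeric(0))
}

as_box_df <- function(d) boxes(d$x_min, d$y_min, d$x_max, d$y_max)
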