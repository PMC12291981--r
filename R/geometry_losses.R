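#' Intersection over Union of paired boxes
#'
#' Computes IoU between boxes paired row-by-row: area of intersection over
#' area of union. Symmetric, bounded in \[0, 1\], equal to 1 only for
#' identical boxes and 0 only for boxes with disjoint interiors.
#'
#' @param a,b Box data frames (see [boxes()]) of equal length, or with one
#'   of them a single box to be recycled.
#' @return A numeric vector of IoU values in \[0, 1\].
#' @examples
#' iou(boxes(0, 0, 2, 2), boxes(1, 1, 3, 3)) # 1/7
#' @seealso [box_iou_matrix()] for all-pairs IoU.
#' @export
iou <- function(a, b) {
  validate_boxes(a)
  validate_boxes(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != nrow(b) && nrow(a) != 1 && nrow(b) != 1) {
    stop("`a` and `b` must have equal numbers of boxes (or one of them a single box)")
  }
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  ix <- pmax(a$x_min[idx_a], b$x_min[idx_b])
  iy <- pmax(a$y_min[idx_a], b$y_min[idx_b])
  ax <- pmin(a$x_max[idx_a], b$x_max[idx_b])
  ay <- pmin(a$y_max[idx_a], b$y_max[idx_b])
  inter <- pmax(0, ax - ix) * pmax(0, ay - iy)
  union <- box_area(a)[idx_a] + box_area(b)[idx_b] - inter
  inter / union
}

#' All-pairs IoU matrix
#'
#' IoU between every box of `a` and every box of `b`, used by the
#' suppression and matching routines.
#'
#' @param a,b Box data frames.
#' @return An `nrow(a)` by `nrow(b)` numeric matrix.
#' @export
box_iou_matrix <- function(a, b) {
  validate_boxes(a)
  validate_boxes(b)
  na <- nrow(a)
  nb <- nrow(b)
  ix <- pmax(matrix(a$x_min, na, nb), matrix(b$x_min, na, nb, byrow = TRUE))
  iy <- pmax(matrix(a$y_min, na, nb), matrix(b$y_min, na, nb, byrow = TRUE))
  ax <- pmin(matrix(a$x_max, na, nb), matrix(b$x_max, na, nb, byrow = TRUE))
  ay <- pmin(matrix(a$y_max, na, nb), matrix(b$y_max, na, nb, byrow = TRUE))
  inter <- pmax(0, ax - ix) * pmax(0, ay - iy)
  union <- outer(box_area(a), box_area(b), `+`) - inter
  inter / union
}

#' Parameters of the penalized IoU score
#'
#' @param alpha Non-negative weight of the shape-disparity penalty;
#'   default 1.
#' @return A list of class `piou_params`.
#' @export
piou_params <- function(alpha = 1) {
  alpha <- as.numeric(alpha)
  stopifnot(length(alpha) == 1, is.finite(alpha), alpha >= 0)
  structure(list(alpha = alpha), class = "piou_params")
}

#' Penalized IoU (PIoU) between predicted and ground-truth boxes
#'
#' Extends IoU with two penalties: a normalized squared center distance and
#' a shape-disparity term,
#' \deqn{PIoU = IoU - \rho^2(c, c_{gt}) / (w^2 + h^2)
#'   - \alpha \, [(w_{gt}-w)^2 + (h_{gt}-h)^2] / (w_{gt}^2 + h_{gt}^2)}
#' where \eqn{w, h} are the predicted box dimensions (the normalization of
#' the center-distance term uses the predicted box, not the enclosing-box
#' diagonal of DIoU-style scores) and \eqn{\rho} is the Euclidean center
#' distance. PIoU never exceeds IoU and equals 1 only for identical boxes.
#'
#' @param pred,gt Box data frames paired row-by-row (recycling a single
#'   box is allowed). `pred` is the predicted box, `gt` the ground truth.
#' @param params A [piou_params()] object.
#' @return A numeric vector of PIoU values (at most 1; may be negative for
#'   badly misplaced boxes).
#' @examples
#' # IoU 1/3, squared center distance 1, predicted w^2+h^2 = 8:
#' piou(boxes(0, 0, 2, 2), boxes(1, 0, 3, 2)) # 1/3 - 1/8
#' @export
piou <- function(pred, gt, params = piou_params()) {
  validate_boxes(pred)
  validate_boxes(gt)
  stopifnot(inherits(params, "piou_params"))
  n <- max(nrow(pred), nrow(gt))
  ip <- rep_len(seq_len(nrow(pred)), n)
  ig <- rep_len(seq_len(nrow(gt)), n)
  w <- box_width(pred)[ip]
  h <- box_height(pred)[ip]
  wg <- box_width(gt)[ig]
  hg <- box_height(gt)[ig]
  cp <- box_center(pred)[ip, , drop = FALSE]
  cg <- box_center(gt)[ig, , drop = FALSE]
  rho2 <- (cp[, 1] - cg[, 1])^2 + (cp[, 2] - cg[, 2])^2
  unname(iou(pred, gt) - rho2 / (w^2 + h^2) -
    params$alpha * ((wg - w)^2 + (hg - h)^2) / (wg^2 + hg^2))
}

#' Parameters of the attention-weighted PIoU v2 loss
#'
#' The v2 loss augments `1 - PIoU` with an attention-weighted geometric
#' penalty. The attention function of IoU and the geometric-penalty
#' function are identified by name so alternative forms can be registered;
#' the defaults are the package's documented surrogates (see
#' [piou_v2_loss()]).
#'
#' @param lam Non-negative attention weight; default 0.5.
#' @param phi_form Name of the attention function of IoU. `"parabolic"`
#'   (the default) is \eqn{\phi(u) = 4u(1-u)}: bounded in \[0, 1\],
#'   maximal at IoU 0.5, vanishing at 0 and 1, so the penalty concentrates
#'   on moderate-overlap pairs (IoU roughly 0.3-0.7).
#' @param psi_form Name of the geometric-penalty function.
#'   `"exp_saturating"` (the default) is \eqn{\psi(\Delta) = 1 -
#'   e^{-\Delta}}: zero at zero disparity, monotone, bounded.
#' @return A list of class `piou_v2_params`.
#' @export
piou_v2_params <- function(lam = 0.5, phi_form = "parabolic",
                           psi_form = "exp_saturating") {
  lam <- as.numeric(lam)
  stopifnot(length(lam) == 1, is.finite(lam), lam >= 0)
  phi_form <- match.arg(phi_form, names(.phi_forms))
  psi_form <- match.arg(psi_form, names(.psi_forms))
  structure(list(lam = lam, phi_form = phi_form, psi_form = psi_form),
            class = "piou_v2_params")
}

.phi_forms <- list(
  parabolic = function(u) 4 * u * (1 - u)
)

.psi_forms <- list(
  exp_saturating = function(d) 1 - exp(-d)
)

#' PIoU v2 regression loss
#'
#' The attention-weighted box regression loss
#' \deqn{L = 1 - PIoU + \lambda \, \phi(IoU) \, \psi(\Delta)}
#' where \eqn{\phi} is a non-monotonic attention function of IoU that puts
#' its weight on moderate-overlap pairs, and \eqn{\psi} penalizes the
#' geometric disparity
#' \deqn{\Delta = \rho^2(c, c_{gt})/d^2
#'   + [(w-w_{gt})^2 + (h-h_{gt})^2] / (w_{gt}^2 + h_{gt}^2)}
#' with \eqn{d} the diagonal of the smallest box enclosing the pair. The
#' loss is non-negative and zero only for identical boxes. Only loss
#' values are exposed; gradients (used when the loss drives detector
#' training) are out of scope.
#'
#' @param pred,gt Box data frames paired row-by-row.
#' @param params A [piou_v2_params()] object (attention weight and the
#'   \eqn{\phi}, \eqn{\psi} forms).
#' @param piou_params A [piou_params()] object for the inner PIoU score.
#' @return A numeric vector of non-negative loss values.
#' @examples
#' piou_v2_loss(boxes(0, 0, 2, 2), boxes(0, 0, 2, 2)) # 0: identical pair
#' @export
piou_v2_loss <- function(pred, gt, params = piou_v2_params(),
                         piou_params = densecount::piou_params()) {
  validate_boxes(pred)
  validate_boxes(gt)
  stopifnot(inherits(params, "piou_v2_params"))
  n <- max(nrow(pred), nrow(gt))
  ip <- rep_len(seq_len(nrow(pred)), n)
  ig <- rep_len(seq_len(nrow(gt)), n)
  w <- box_width(pred)[ip]
  h <- box_height(pred)[ip]
  wg <- box_width(gt)[ig]
  hg <- box_height(gt)[ig]
  cp <- box_center(pred)[ip, , drop = FALSE]
  cg <- box_center(gt)[ig, , drop = FALSE]
  rho2 <- (cp[, 1] - cg[, 1])^2 + (cp[, 2] - cg[, 2])^2
  # enclosing-box diagonal normalizes the center term so Delta is scale-free
  ew <- pmax(pred$x_max[ip], gt$x_max[ig]) - pmin(pred$x_min[ip], gt$x_min[ig])
  eh <- pmax(pred$y_max[ip], gt$y_max[ig]) - pmin(pred$y_min[ip], gt$y_min[ig])
  d2 <- ew^2 + eh^2
  delta <- rho2 / d2 + ((w - wg)^2 + (h - hg)^2) / (wg^2 + hg^2)
  phi <- .phi_forms[[params$phi_form]]
  psi <- .psi_forms[[params$psi_form]]
  unname(1 - piou(pred, gt, piou_params) +
    params$lam * phi(iou(pred, gt)) * psi(delta))
}
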