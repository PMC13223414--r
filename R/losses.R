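# Bounding-box regression losses (IoU family through EIoU), the focal
# classification loss with a difficulty scale factor, and the composite
# detection objective.

#' EIoU bounding-box regression loss
#'
#' Three-part loss: `1 - IoU`, a center-distance term `rho^2 / c^2` (with
#' `c^2` the squared diagonal of the smallest enclosing box), and an
#' edge-length term `(w - w_gt)^2 / c_w^2 + (h - h_gt)^2 / c_h^2` with
#' `c_w`, `c_h` the enclosing box's width and height. Penalizing the edge
#' lengths directly (rather than an aspect ratio) keeps the width and height
#' gradients independent, which is what gives the loss its fast convergence.
#'
#' @param pred Predicted box; may be degenerate.
#' @param gt Ground-truth box with positive area.
#' @return List with `iou_term`, `distance_term`, `aspect_term`, `total`.
#' @export
eiou_loss <- function(pred, gt) {
  pred <- validate_box(pred); gt <- validate_box(gt)
  if (identical(pred, gt))
    return(list(iou_term = 0, distance_term = 0, aspect_term = 0, total = 0))
  if (box_area(gt) <= 0)
    stop("ground-truth box must have positive area")
  enc <- enclosing_box(pred, gt)
  cw <- enc[3] - enc[1]; ch <- enc[4] - enc[2]
  c2 <- cw^2 + ch^2
  if (c2 <= 0) stop("degenerate enclosing box for distinct inputs")
  pc <- c((pred[1] + pred[3]) / 2, (pred[2] + pred[4]) / 2)
  gc <- c((gt[1] + gt[3]) / 2, (gt[2] + gt[4]) / 2)
  rho2 <- sum((pc - gc)^2)
  iou_term <- 1 - box_iou(pred, gt)
  distance_term <- rho2 / c2
  aspect_term <- ((pred[3] - pred[1]) - (gt[3] - gt[1]))^2 / cw^2 +
    ((pred[4] - pred[2]) - (gt[4] - gt[2]))^2 / ch^2
  list(iou_term = iou_term, distance_term = distance_term,
       aspect_term = aspect_term,
       total = iou_term + distance_term + aspect_term)
}

#' GIoU bounding-box regression loss (reference)
#' @inheritParams eiou_loss
#' @return `1 - IoU + (|C| - |U|) / |C|` with `C` the enclosing box.
#' @export
giou_loss <- function(pred, gt) {
  pred <- validate_box(pred); gt <- validate_box(gt)
  enc <- enclosing_box(pred, gt)
  ca <- box_area(enc)
  iou <- box_iou(pred, gt)
  iw <- max(min(pred[3], gt[3]) - max(pred[1], gt[1]), 0)
  ih <- max(min(pred[4], gt[4]) - max(pred[2], gt[2]), 0)
  un <- box_area(pred) + box_area(gt) - iw * ih
  pen <- if (ca > 0) (ca - un) / ca else 0
  1 - iou + pen
}

#' DIoU bounding-box regression loss (reference)
#' @inheritParams eiou_loss
#' @export
diou_loss <- function(pred, gt) {
  pred <- validate_box(pred); gt <- validate_box(gt)
  enc <- enclosing_box(pred, gt)
  c2 <- (enc[3] - enc[1])^2 + (enc[4] - enc[2])^2
  pc <- c((pred[1] + pred[3]) / 2, (pred[2] + pred[4]) / 2)
  gc <- c((gt[1] + gt[3]) / 2, (gt[2] + gt[4]) / 2)
  pen <- if (c2 > 0) sum((pc - gc)^2) / c2 else 0
  1 - box_iou(pred, gt) + pen
}

#' CIoU bounding-box regression loss (comparison baseline)
#'
#' Standard complete-IoU value: `1 - IoU + rho^2/c^2 + alpha_v * v` with the
#' aspect-consistency term `v = (4/pi^2) (atan(w_gt/h_gt) - atan(w/h))^2` and
#' `alpha_v = v / ((1 - IoU) + v)` treated as a constant weight. Its known
#' pathology — the width and height gradients of `v` always have opposite
#' signs, so both edges cannot grow or shrink together — is exposed through
#' [ciou_aspect_gradients()].
#'
#' @inheritParams eiou_loss
#' @export
ciou_loss <- function(pred, gt) {
  pred <- validate_box(pred); gt <- validate_box(gt)
  if (box_area(pred) <= 0 || box_area(gt) <= 0)
    stop("CIoU requires positive-area boxes")
  base <- diou_loss(pred, gt)
  v <- .ciou_v(pred[3] - pred[1], pred[4] - pred[2],
               gt[3] - gt[1], gt[4] - gt[2])
  iou <- box_iou(pred, gt)
  alpha_v <- if (v > 0) v / ((1 - iou) + v) else 0
  base + alpha_v * v
}

.ciou_v <- function(w, h, wg, hg) {
  (4 / pi^2) * (atan(wg / hg) - atan(w / h))^2
}

#' Finite-difference gradients of the CIoU aspect term
#'
#' Central-difference estimates of the partial derivatives of `v` with
#' respect to the predicted width and height; whenever the aspect ratios
#' differ the two are of opposite sign.
#'
#' @inheritParams eiou_loss
#' @param h_step Finite-difference step.
#' @return `c(dv_dw, dv_dh)`.
#' @export
ciou_aspect_gradients <- function(pred, gt, h_step = 1e-5) {
  pred <- validate_box(pred); gt <- validate_box(gt)
  w <- pred[3] - pred[1]; h <- pred[4] - pred[2]
  wg <- gt[3] - gt[1]; hg <- gt[4] - gt[2]
  dv_dw <- (.ciou_v(w + h_step, h, wg, hg) -
              .ciou_v(w - h_step, h, wg, hg)) / (2 * h_step)
  dv_dh <- (.ciou_v(w, h + h_step, wg, hg) -
              .ciou_v(w, h - h_step, wg, hg)) / (2 * h_step)
  c(dv_dw = dv_dw, dv_dh = dv_dh)
}

#' Central-difference gradient of a box loss w.r.t. the predicted box
#' @param loss_fn Function `(pred, gt) -> scalar` (or the `$total` of
#'   [eiou_loss()]-style lists).
#' @inheritParams eiou_loss
#' @param h Step size.
#' @return Length-4 gradient in `(x_min, y_min, x_max, y_max)`.
#' @export
box_loss_gradient <- function(loss_fn, pred, gt, h = 1e-3) {
  val <- function(b) {
    r <- loss_fn(b, gt)
    if (is.list(r)) r$total else r
  }
  g <- numeric(4)
  for (k in 1:4) {
    bp <- pred; bm <- pred
    bp[k] <- bp[k] + h; bm[k] <- bm[k] - h
    # keep the perturbed boxes valid
    if (bp[3] < bp[1]) bp[3] <- bp[1]
    if (bp[4] < bp[2]) bp[4] <- bp[2]
    if (bm[3] < bm[1]) bm[3] <- bm[1]
    if (bm[4] < bm[2]) bm[4] <- bm[2]
    g[k] <- (val(bp) - val(bm)) / (2 * h)
  }
  g
}

#' Gradient descent on a box-regression objective
#'
#' Plain gradient descent on the four box coordinates using central
#' finite differences, run until the predicted box reaches the target IoU
#' or the iteration cap. Used to compare convergence speed of the IoU-family
#' losses from identical anchors.
#'
#' @inheritParams box_loss_gradient
#' @param start Initial box.
#' @param lr Step size.
#' @param target_iou Stopping IoU (default 0.99).
#' @param max_iter Iteration cap.
#' @return List with `iterations` (NA if the cap was hit) and `final_box`.
#' @export
descend_box_loss <- function(loss_fn, start, gt, lr = 0.1,
                             target_iou = 0.99, max_iter = 5000) {
  box <- validate_box(start)
  for (it in seq_len(max_iter)) {
    if (box_iou(box, gt) >= target_iou)
      return(list(iterations = it - 1L, final_box = box))
    g <- box_loss_gradient(loss_fn, box, gt)
    box <- box - lr * g
    if (box[3] < box[1]) box[c(1, 3)] <- mean(box[c(1, 3)])
    if (box[4] < box[2]) box[c(2, 4)] <- mean(box[c(2, 4)])
  }
  list(iterations = NA_integer_, final_box = box)
}

#' Configuration of the focal classification loss
#'
#' @param gamma Focusing exponent; down-weights well-classified samples.
#' @param alpha Sensitivity of the difficulty scale factor
#'   `s = (1 - p)^alpha` for positives and `s = p^alpha` for negatives.
#' @return A `cls_loss_config` list.
#' @export
cls_loss_config <- function(gamma = 2, alpha = 0.5) {
  stopifnot(gamma >= 0, alpha >= 0)
  structure(list(gamma = gamma, alpha = alpha), class = "cls_loss_config")
}

.clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Focal classification loss with a difficulty scale factor
#'
#' Per sample `-s (1 - p_t)^gamma log(p_t)` with `p_t = p` for positives
#' (`t = 1`) and `1 - p` for negatives (`t = 0`); the scale factor `s`
#' raises the weight of hard samples and suppresses easy ones. The sum over
#' all samples is normalized by the number of positives (floor 1).
#'
#' @param p Predicted probabilities (clamped into `(0, 1)`).
#' @param t Binary indicators, 1 for positive samples.
#' @param cfg A [cls_loss_config()].
#' @return Nonnegative scalar loss.
#' @export
focal_classification_loss <- function(p, t, cfg = cls_loss_config()) {
  stopifnot(length(p) == length(t), all(t %in% c(0, 1)))
  p <- .clamp_prob(p)
  n_pos <- max(sum(t == 1), 1)
  pt <- ifelse(t == 1, p, 1 - p)
  s <- (1 - pt)^cfg$alpha
  sum(-s * (1 - pt)^cfg$gamma * log(pt)) / n_pos
}

# d(loss)/d(p) of the focal loss, per element, WITHOUT the 1/N_pos factor.
.focal_grad_p <- function(p, t, cfg) {
  p <- .clamp_prob(p)
  e <- cfg$gamma + cfg$alpha
  gpos <- e * (1 - p)^(pmax(e - 1, 0)) * log(p) - (1 - p)^e / p
  gneg <- -e * p^(pmax(e - 1, 0)) * log(1 - p) + p^e / (1 - p)
  ifelse(t == 1, gpos, gneg)
}

#' Weighted binary cross-entropy over dense elements
#'
#' Mean over all N elements of `-[y log(p) + (1 - y) log(1 - p)]`, each term
#' optionally multiplied by a weight. Provided as an optional auxiliary
#' objective; it is off by default in training.
#'
#' @param pred Predicted probabilities.
#' @param truth Binary labels of the same length.
#' @param weight Scalar or per-element weight `s`.
#' @return Nonnegative scalar.
#' @export
weighted_bce <- function(pred, truth, weight = 1) {
  if (length(pred) != length(truth))
    stop("pred and truth lengths differ (", length(pred), " vs ",
         length(truth), ")")
  p <- .clamp_prob(pred)
  mean(weight * (-(truth * log(p) + (1 - truth) * log(1 - p))))
}

#' Composite detection loss
#'
#' `total = w_cls * cls + w_reg * reg` where `cls` is the focal loss over
#' every anchor/class score and `reg` the mean EIoU total over the positive
#' anchors (0 when there are none).
#'
#' @param scores n_anchor x n_class matrix of predicted probabilities.
#' @param target n_anchor x n_class binary matrix (1 at a positive anchor's
#'   matched class).
#' @param pred_boxes Matrix of decoded boxes for the positive anchors.
#' @param gt_boxes Matching ground-truth boxes, same row count.
#' @param cfg A [cls_loss_config()].
#' @param w_cls,w_reg Component weights (default 1 and 1).
#' @param reg_loss_fn Box loss, default [eiou_loss()].
#' @return List `cls_loss`, `reg_loss`, `total`.
#' @export
total_detection_loss <- function(scores, target, pred_boxes = NULL,
                                 gt_boxes = NULL, cfg = cls_loss_config(),
                                 w_cls = 1, w_reg = 1,
                                 reg_loss_fn = eiou_loss) {
  n_pos <- sum(rowSums(matrix(target, nrow = NROW(scores))) > 0)
  cls <- focal_classification_loss(as.numeric(scores), as.numeric(target), cfg)
  reg <- 0
  if (n_pos > 0 && !is.null(pred_boxes) && NROW(pred_boxes) > 0) {
    vals <- vapply(seq_len(NROW(pred_boxes)), function(k) {
      r <- reg_loss_fn(pred_boxes[k, ], gt_boxes[k, ])
      if (is.list(r)) r$total else r
    }, numeric(1))
    reg <- mean(vals)
  }
  list(cls_loss = cls, reg_loss = reg, total = w_cls * cls + w_reg * reg)
}
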