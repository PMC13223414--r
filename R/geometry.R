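# Box algebra shared by the losses, head, assigner and evaluation code.
#
# A box is a numeric vector c(x_min, y_min, x_max, y_max) in continuous pixel
# coordinates (origin top-left, x rightward, y downward); sets of boxes are
# n x 4 matrices. Widths are x_max - x_min with no "+1" pixel convention, so
# all IoU-type quantities are scale-free. Degenerate zero-area boxes are legal
# (they arise from zero regressed distances) and contribute 0 to IoU.

validate_box <- function(box) {
  box <- as.numeric(box)
  if (length(box) != 4 || anyNA(box))
    stop("a box must be four finite numbers (x_min, y_min, x_max, y_max)")
  if (box[3] < box[1] || box[4] < box[2])
    stop("invalid box: max coordinate smaller than min (",
         paste(signif(box, 6), collapse = ", "), ")")
  box
}

box_area <- function(box) {
  (box[3] - box[1]) * (box[4] - box[2])
}

#' Intersection over union of two boxes
#'
#' Ratio of the intersection area to the union area of two axis-aligned
#' boxes. Returns 0 when the boxes are disjoint or when the union has zero
#' area (two coincident degenerate boxes).
#'
#' @param a,b Boxes as `c(x_min, y_min, x_max, y_max)`.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
box_iou <- function(a, b) {
  a <- validate_box(a); b <- validate_box(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  un <- box_area(a) + box_area(b) - inter
  if (un <= 0) return(0)
  inter / un
}

#' IoU between each row of a box matrix and one box
#' @param boxes n x 4 matrix; @param box a single box.
#' @return Numeric vector of length n.
#' @export
box_iou_many <- function(boxes, box) {
  boxes <- matrix(boxes, ncol = 4)
  iw <- pmin(boxes[, 3], box[3]) - pmax(boxes[, 1], box[1])
  ih <- pmin(boxes[, 4], box[4]) - pmax(boxes[, 2], box[2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  un <- (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2]) +
    (box[3] - box[1]) * (box[4] - box[2]) - inter
  ifelse(un > 0, inter / un, 0)
}

#' Smallest box enclosing two boxes
#' @inheritParams box_iou
#' @return The componentwise min/max hull box.
#' @export
enclosing_box <- function(a, b) {
  a <- validate_box(a); b <- validate_box(b)
  c(min(a[1], b[1]), min(a[2], b[2]), max(a[3], b[3]), max(a[4], b[4]))
}

#' Decode four boundary distances at an anchor point into a box
#'
#' Anchor-free detectors regress each box as four nonnegative distances
#' (left, top, right, bottom) from a grid anchor point.
#'
#' @param point Anchor point `c(x, y)` in image coordinates.
#' @param distances Nonnegative `c(l, t, r, b)`.
#' @return A box `c(x - l, y - t, x + r, y + b)`.
#' @export
decode_distances <- function(point, distances) {
  distances <- as.numeric(distances)
  if (length(distances) != 4 || any(distances < 0))
    stop("distances must be four nonnegative numbers (l, t, r, b)")
  c(point[1] - distances[1], point[2] - distances[2],
    point[1] + distances[3], point[2] + distances[4])
}

#' Encode a box as boundary distances from an anchor point
#' @inheritParams decode_distances
#' @param box A valid box containing conceptually the anchor point.
#' @return `c(l, t, r, b)` such that [decode_distances()] round-trips.
#' @export
encode_distances <- function(box, point) {
  box <- validate_box(box)
  c(point[1] - box[1], point[2] - box[2], box[3] - point[1], box[4] - point[2])
}

#' Anchor points of a feature level
#'
#' Grid cell (i, j) (1-based) of a stride-s level maps to the image-space
#' point ((j - 0.5) s, (i - 0.5) s).
#'
#' @param h,w Feature map height and width.
#' @param stride Level stride in pixels.
#' @return Data frame with columns `x`, `y`, `i`, `j`, `stride`.
#' @export
anchor_points <- function(h, w, stride) {
  grid <- expand.grid(i = seq_len(h), j = seq_len(w))
  data.frame(x = (grid$j - 0.5) * stride, y = (grid$i - 0.5) * stride,
             i = grid$i, j = grid$j, stride = stride)
}

#' Greedy class-wise non-maximum suppression
#'
#' Detections are processed per class in descending score order (ties broken
#' by lower original index); a detection is suppressed when its IoU with an
#' already kept same-class detection exceeds the threshold.
#'
#' @param detections Data frame with columns `x_min,y_min,x_max,y_max,class,score`.
#' @param iou_threshold Suppression IoU threshold (default 0.6).
#' @return The surviving subset, ordered by descending score.
#' @export
nms <- function(detections, iou_threshold = 0.6) {
  if (is.null(detections) || nrow(detections) == 0) return(detections)
  stopifnot(all(detections$score >= 0 & detections$score <= 1))
  boxes <- as.matrix(detections[, c("x_min", "y_min", "x_max", "y_max")])
  keep <- logical(nrow(detections))
  for (cl in unique(detections$class)) {
    idx <- which(detections$class == cl)
    ord <- idx[order(-detections$score[idx], idx)]
    while (length(ord)) {
      top <- ord[1]
      keep[top] <- TRUE
      ord <- ord[-1]
      if (!length(ord)) break
      ious <- box_iou_many(boxes[ord, , drop = FALSE], boxes[top, ])
      ord <- ord[ious <= iou_threshold]
    }
  }
  out <- detections[keep, , drop = FALSE]
  out[order(-out$score, which(keep)), , drop = FALSE]
}
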