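# Task-aligned sample assignment (TAL).
#
# For every ground-truth instance, anchors whose point falls inside the box
# are candidates; they are ranked by the alignment metric
# m = score^alpha * IoU^beta (score taken at the instance's class from the
# aligned score map, IoU between the anchor's decoded box and the instance)
# and the top-k become positive. An anchor claimed by several instances goes
# to the one with the highest m. A ground truth with no interior anchor
# falls back to its closest anchor by center distance, and one whose
# candidates were all claimed by other instances reclaims its best
# candidate, so no instance is left unsupervised. Soft classification
# targets are the metric values normalized per instance to its maximum IoU.

#' Task-aligned anchor assignment
#'
#' @param anchors Data frame with columns `x`, `y` (one row per anchor,
#'   across all pyramid levels).
#' @param scores n_anchor x n_class matrix of predicted (aligned) scores.
#' @param boxes n_anchor x 4 matrix of decoded (aligned) boxes.
#' @param gt Data frame `x_min,y_min,x_max,y_max,class_idx` (1-based class).
#' @param alpha,beta Metric exponents (defaults 1 and 6).
#' @param topk Candidates kept per instance (default 13).
#' @return List: `positive` (logical), `gt_index` (NA for negatives),
#'   `soft_target` (alignment-normalized target in `[0, 1]`), `n_pos`,
#'   `n_neg`, and `target` (n_anchor x n_class binary matrix).
#' @export
tal_assign <- function(anchors, scores, boxes, gt, alpha = 1, beta = 6,
                       topk = 13) {
  n <- nrow(anchors)
  n_class <- ncol(scores)
  positive <- logical(n)
  gt_index <- rep(NA_integer_, n)
  soft <- numeric(n)
  best_m <- rep(-Inf, n)
  if (!is.null(gt) && nrow(gt) > 0) {
    cand_of <- list()
    m_of <- list()
    norm_of <- numeric(nrow(gt))
    for (g in seq_len(nrow(gt))) {
      gb <- as.numeric(gt[g, c("x_min", "y_min", "x_max", "y_max")])
      inside <- anchors$x > gb[1] & anchors$x < gb[3] &
        anchors$y > gb[2] & anchors$y < gb[4]
      cand <- which(inside)
      if (!length(cand)) {
        cx <- (gb[1] + gb[3]) / 2; cy <- (gb[2] + gb[4]) / 2
        cand <- which.min((anchors$x - cx)^2 + (anchors$y - cy)^2)
      }
      iou <- box_iou_many(boxes[cand, , drop = FALSE], gb)
      m <- scores[cand, gt$class_idx[g]]^alpha * iou^beta
      m[!is.finite(m)] <- 0
      ord <- order(-m, cand)
      keep <- ord[seq_len(min(topk, length(cand)))]
      sel <- cand[keep]
      m_sel <- m[keep]
      iou_sel <- iou[keep]
      norm <- if (max(m_sel) > 0) max(iou_sel) / max(m_sel) else 0
      cand_of[[g]] <- sel
      m_of[[g]] <- m_sel
      norm_of[g] <- norm
      for (k in seq_along(sel)) {
        a <- sel[k]
        if (m_sel[k] > best_m[a]) {
          best_m[a] <- m_sel[k]
          positive[a] <- TRUE
          gt_index[a] <- g
          soft[a] <- m_sel[k] * norm
        }
      }
    }
    # reclaim pass: an instance whose candidates were all claimed by other
    # instances takes back its best candidate whose current owner keeps at
    # least one anchor (its best candidate outright if none qualifies)
    for (g in seq_len(nrow(gt))) {
      if (any(gt_index == g, na.rm = TRUE)) next
      sel <- cand_of[[g]]
      m_sel <- m_of[[g]]
      ok <- vapply(seq_along(sel), function(k) {
        own <- gt_index[sel[k]]
        is.na(own) || sum(gt_index == own, na.rm = TRUE) > 1
      }, logical(1))
      pool <- if (any(ok)) which(ok) else seq_along(sel)
      k <- pool[which.max(m_sel[pool])]
      a <- sel[k]
      positive[a] <- TRUE
      gt_index[a] <- g
      soft[a] <- m_sel[k] * norm_of[g]
      best_m[a] <- m_sel[k]
    }
  }
  target <- matrix(0, n, n_class)
  pos_idx <- which(positive)
  if (length(pos_idx))
    target[cbind(pos_idx, gt$class_idx[gt_index[pos_idx]])] <- 1
  list(positive = positive, gt_index = gt_index, soft_target = soft,
       n_pos = sum(positive), n_neg = n - sum(positive), target = target)
}
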