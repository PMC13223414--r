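# Independent brute-force oracles used by both the module tests and the
# acceptance suite.

# quadratic-time reference suppression, written directly from the rule
reference_nms <- function(det, thr) {
  keep <- logical(nrow(det))
  for (cl in unique(det$class)) {
    idx <- which(det$class == cl)
    ord <- idx[order(-det$score[idx], idx)]
    for (i in seq_along(ord)) {
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        if (!keep[ord[j]]) next
        if (box_iou(as.numeric(det[ord[i], 1:4]),
                    as.numeric(det[ord[j], 1:4])) > thr) ok <- FALSE
      }
      keep[ord[i]] <- ok
    }
  }
  sort(which(keep))
}

# exhaustive enumeration of the task-aligned assignment rule (candidate
# ranking, conflict resolution, starvation reclaim)
reference_tal <- function(anchors, scores, boxes, gt, alpha, beta, topk) {
  n <- nrow(anchors)
  best_m <- rep(-Inf, n); gt_of <- rep(NA_integer_, n)
  cands <- list(); ms <- list()
  for (g in seq_len(NROW(gt))) {
    gb <- as.numeric(gt[g, c("x_min", "y_min", "x_max", "y_max")])
    cand <- which(anchors$x > gb[1] & anchors$x < gb[3] &
                    anchors$y > gb[2] & anchors$y < gb[4])
    if (!length(cand)) {
      cx <- (gb[1] + gb[3]) / 2; cy <- (gb[2] + gb[4]) / 2
      cand <- which.min((anchors$x - cx)^2 + (anchors$y - cy)^2)
    }
    m <- vapply(cand, function(a)
      scores[a, gt$class_idx[g]]^alpha *
        box_iou(boxes[a, ], gb)^beta, numeric(1))
    pick <- order(-m, cand)[seq_len(min(topk, length(cand)))]
    cands[[g]] <- cand[pick]; ms[[g]] <- m[pick]
    for (k in seq_along(pick)) {
      a <- cand[pick[k]]; mv <- m[pick[k]]
      if (mv > best_m[a]) {
        best_m[a] <- mv
        gt_of[a] <- g
      }
    }
  }
  for (g in seq_len(NROW(gt))) {
    if (any(gt_of == g, na.rm = TRUE)) next
    ok <- vapply(seq_along(cands[[g]]), function(k) {
      own <- gt_of[cands[[g]][k]]
      is.na(own) || sum(gt_of == own, na.rm = TRUE) > 1
    }, logical(1))
    pool <- if (any(ok)) which(ok) else seq_along(cands[[g]])
    k <- pool[which.max(ms[[g]][pool])]
    gt_of[cands[[g]][k]] <- g
  }
  gt_of
}

make_toy <- function(seed, n_anchor = 12, n_gt = 2) {
  withr::with_seed(seed, {
    anchors <- data.frame(x = runif(n_anchor, 0, 32),
                          y = runif(n_anchor, 0, 32))
    scores <- matrix(runif(n_anchor * 5, 0.01, 0.99), n_anchor, 5)
    boxes <- t(vapply(seq_len(n_anchor), function(i) {
      c(anchors$x[i] - runif(1, 1, 6), anchors$y[i] - runif(1, 1, 6),
        anchors$x[i] + runif(1, 1, 6), anchors$y[i] + runif(1, 1, 6))
    }, numeric(4)))
    gt <- data.frame(x_min = runif(n_gt, 0, 16), y_min = runif(n_gt, 0, 16))
    gt$x_max <- gt$x_min + runif(n_gt, 8, 14)
    gt$y_max <- gt$y_min + runif(n_gt, 8, 14)
    gt$class_idx <- sample(5, n_gt, TRUE)
    list(anchors = anchors, scores = scores, boxes = boxes, gt = gt)
  })
}
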