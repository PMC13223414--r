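det_row <- function(x1, y1, x2, y2, cl, sc) {
  data.frame(x_min = x1, y_min = y1, x_max = x2, y_max = y2,
             class = cl, score = sc)
}

test_that("detection matching follows the strict-IoU class-aware rule", {
  gt <- det_row(0, 0, 10, 10, "K1", NA)[, 1:5]
  hit <- match_detections(det_row(0, 0, 10, 10, "K1", 0.9), gt, 0.5)
  expect_equal(hit$TP, 1); expect_equal(hit$FP, 0); expect_equal(hit$FN, 0)
  # IoU 0.4 against threshold 0.5: invalid, detection FP and gt missed
  off <- det_row(0, 0, 10, 4, "K1", 0.9)
  expect_equal(box_iou(as.numeric(off[1, 1:4]), as.numeric(gt[1, 1:4])),
               0.4)
  miss <- match_detections(off, gt, 0.5)
  expect_equal(miss$TP, 0); expect_equal(miss$FP, 1); expect_equal(miss$FN, 1)
  # exact-threshold IoU is invalid (strict inequality)
  half <- det_row(0, 0, 10, 5, "K1", 0.9)
  expect_equal(match_detections(half, gt, 1 / 3)$TP, 1)
  expect_equal(match_detections(half, gt, 0.5)$TP, 0)
  # wrong class never matches
  wrong <- match_detections(det_row(0, 0, 10, 10, "K2", 0.9), gt, 0.5)
  expect_equal(wrong$TP, 0)
})

test_that("greedy matching equals a brute-force assignment on a seeded
           toy and counts are conserved", {
  withr::with_seed(17, {
    gts <- do.call(rbind, lapply(1:3, function(i)
      det_row(runif(1, 0, 20), runif(1, 0, 20), NA, NA, "K2", NA)[, 1:5]))
    gts$x_max <- gts$x_min + 8; gts$y_max <- gts$y_min + 8
    dets <- do.call(rbind, lapply(1:5, function(i) {
      g <- gts[sample(3, 1), ]
      det_row(g$x_min + runif(1, -3, 3), g$y_min + runif(1, -3, 3),
              g$x_max + runif(1, -3, 3), g$y_max + runif(1, -3, 3),
              "K2", round(runif(1), 3))
    }))
  })
  mo <- match_detections(dets, gts, 0.5)
  expect_equal(mo$TP + mo$FP, nrow(dets))
  expect_equal(mo$TP + mo$FN, nrow(gts))
  # brute force: walk detections by descending score, each takes its best
  # still-free gt over the threshold
  taken <- logical(3); tp_ref <- logical(5)
  for (d in order(-dets$score, 1:5)) {
    ious <- vapply(1:3, function(g)
      box_iou(as.numeric(dets[d, 1:4]), as.numeric(gts[g, 1:4])),
      numeric(1))
    ious[taken] <- -1
    if (max(ious) > 0.5) {
      taken[which.max(ious)] <- TRUE
      tp_ref[d] <- TRUE
    }
  }
  expect_equal(mo$tp, tp_ref)
  # nested TP sets across thresholds
  mo75 <- match_detections(dets, gts, 0.75)
  expect_true(all(which(mo75$tp) %in% which(mo$tp)))
})

test_that("precision and recall follow the stated conventions", {
  expect_equal(unname(precision_recall(list(TP = 8, FP = 2, FN = 0))),
               c(0.8, 1))
  expect_equal(unname(precision_recall(list(TP = 8, FP = 0, FN = 2))),
               c(1, 0.8))
  expect_equal(unname(precision_recall(list(TP = 0, FP = 0, FN = 0))),
               c(0, 1))
})

# exhaustive oracle: interpolated precision at every achieved recall,
# integrated stepwise
ap_oracle <- function(scores, tp, n_gt) {
  ord <- order(-scores)
  rec <- cumsum(tp[ord]) / n_gt
  prec <- cumsum(tp[ord]) / seq_along(scores)
  p_at <- function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }
  levels <- sort(unique(c(0, rec)))
  ap <- 0
  for (i in seq_len(length(levels) - 1))
    ap <- ap + (levels[i + 1] - levels[i]) * p_at(levels[i + 1])
  ap
}

test_that("average precision matches hand-traced and oracle values", {
  expect_equal(average_precision(0.9, TRUE, 1), 1)
  # 2 gt; score order TP, FP, TP -> PR points (.5,1), (.5,.5), (1, 2/3);
  # monotone interpolation gives .5*1 + .5*2/3
  sc <- c(0.9, 0.8, 0.7); tp <- c(TRUE, FALSE, TRUE)
  expect_equal(average_precision(sc, tp, 2), 0.5 + 0.5 * 2 / 3,
               tolerance = 1e-12)
  expect_equal(average_precision(sc, tp, 2), ap_oracle(sc, tp, 2),
               tolerance = 1e-12)
  withr::with_seed(23, {
    for (k in 1:10) {
      n <- sample(3:12, 1)
      sc <- round(runif(n), 3)
      tp <- as.logical(rbinom(n, 1, 0.6))
      n_gt <- sum(tp) + sample(0:3, 1)
      if (n_gt == 0) next
      expect_equal(average_precision(sc, tp, n_gt),
                   ap_oracle(sc, tp, n_gt), tolerance = 1e-12)
    }
  })
  # rank statistic: invariant to monotone score rescaling
  expect_equal(average_precision(sc / 2 + 0.1, tp, 2),
               average_precision(sc, tp, 2))
  # a zero-score FP never increases AP
  expect_lte(average_precision(c(sc, 0), c(tp, FALSE), 2),
             average_precision(sc, tp, 2))
  expect_true(is.na(average_precision(numeric(0), logical(0), 0)))
})

test_that("mAP averages defined classes and FPS is the stated
           reciprocal", {
  expect_equal(mean_average_precision(c(1, 0.5)), 0.75)
  expect_equal(mean_average_precision(c(0.7, NA)), 0.7)
  expect_equal(mean_average_precision(c(K3 = 0.4)), 0.4)
  expect_error(mean_average_precision(c(NA_real_, NA_real_)), "undefined")
  expect_equal(detection_fps(0.05), 20)
  expect_equal(detection_fps(1), 1)
  expect_equal(detection_fps(1 / detection_fps(0.37)), 1 / 0.37,
               tolerance = 1e-12)
  expect_error(detection_fps(0), "positive")
})

test_that("the confusion matrix attributes each gt to its best overlapping
           detection", {
  gts <- do.call(rbind, lapply(0:4, function(k)
    det_row(10 * k, 0, 10 * k + 8, 8, paste0("K", k), NA)[, 1:5]))
  perfect <- lapply(seq_len(nrow(gts)), function(i)
    list(dets = det_row(gts$x_min[i], 0, gts$x_max[i], 8,
                        gts$class[i], 0.9),
         gts = gts[i, ]))
  cm <- confusion_matrix_detections(perfect)
  expect_equal(unname(diag(cm[, 1:5])), rep(1, 5))
  # right place, wrong class: zero diagonal
  shifted <- lapply(seq_len(nrow(gts)), function(i)
    list(dets = det_row(gts$x_min[i], 0, gts$x_max[i], 8,
                        paste0("K", (i %% 5)), 0.9),
         gts = gts[i, ]))
  cm2 <- confusion_matrix_detections(shifted)
  expect_equal(sum(diag(cm2[, 1:5])), 0)
  expect_equal(unname(rowSums(cm2)), rep(1, 5))
  # missed gt goes to the "missed" column
  none <- list(list(dets = det_row(0, 0, 1, 1, "K0", 0.5)[0, ],
                    gts = gts[1, ]))
  cm3 <- confusion_matrix_detections(none)
  expect_equal(unname(cm3["K0", "missed"]), 1)
})

test_that("raising the IoU threshold never raises AP on seeded
           detections", {
  withr::with_seed(31, {
    gts <- do.call(rbind, lapply(1:6, function(i) {
      x <- runif(1, 0, 40); y <- runif(1, 0, 40)
      det_row(x, y, x + 10, y + 10, "K1", NA)[, 1:5]
    }))
    dets <- do.call(rbind, lapply(1:10, function(i) {
      g <- gts[sample(6, 1), ]
      j <- runif(4, -2.5, 2.5)
      det_row(g$x_min + j[1], g$y_min + j[2], g$x_max + j[3],
              g$y_max + j[4], "K1", round(runif(1), 3))
    }))
  })
  aps <- vapply(c(0.3, 0.5, 0.75, 0.9), function(thr) {
    mo <- match_detections(dets, gts, thr)
    average_precision(dets$score, mo$tp, nrow(gts))
  }, numeric(1))
  expect_false(is.unsorted(rev(aps)))
})
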