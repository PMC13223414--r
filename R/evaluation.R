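# VOC-style detection metrics: greedy matching, precision/recall, AP by
# area under the monotone-interpolated PR curve, mAP, FPS and a per-grade
# confusion matrix.

#' Match detections against ground truth at one IoU threshold
#'
#' Detections are processed in descending score order; one is a true
#' positive iff its class equals a ground truth's class and their IoU is
#' strictly greater than the threshold, and that ground truth is still
#' unmatched (each ground truth absorbs at most one detection).
#'
#' @param dets Data frame `x_min,y_min,x_max,y_max,class,score`.
#' @param gts Data frame `x_min,y_min,x_max,y_max,class` (one image).
#' @param iou_threshold Matching threshold (default 0.5).
#' @return List: `tp` logical per detection (score-descending order kept in
#'   `order`), `gt_matched` logical per ground truth, plus TP/FP/FN counts.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  n_det <- NROW(dets); n_gt <- NROW(gts)
  tp <- logical(n_det)
  det_gt <- rep(NA_integer_, n_det)
  gt_matched <- logical(n_gt)
  ord <- if (n_det) order(-dets$score, seq_len(n_det)) else integer(0)
  for (d in ord) {
    if (!n_gt) break
    same <- which(!gt_matched & gts$class == dets$class[d])
    if (!length(same)) next
    ious <- box_iou_many(
      as.matrix(gts[same, c("x_min", "y_min", "x_max", "y_max")]),
      as.numeric(dets[d, c("x_min", "y_min", "x_max", "y_max")]))
    best <- which.max(ious)
    if (ious[best] > iou_threshold) {
      tp[d] <- TRUE
      det_gt[d] <- same[best]
      gt_matched[same[best]] <- TRUE
    }
  }
  list(tp = tp, det_gt = det_gt, gt_matched = gt_matched, order = ord,
       TP = sum(tp), FP = n_det - sum(tp), FN = n_gt - sum(gt_matched))
}

#' Precision and recall from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`; the empty cases are defined as
#' precision 0 (no detections) and recall 1 (no ground truth).
#'
#' @param outcome A [match_detections()] result or a list with TP/FP/FN.
#' @return `c(precision, recall)`.
#' @export
precision_recall <- function(outcome) {
  tp <- outcome$TP; fp <- outcome$FP; fn <- outcome$FN
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 1
  c(precision = p, recall = r)
}

#' Average precision for one class
#'
#' Sweeps the score threshold over the pooled detections of one class,
#' traces the (recall, precision) curve and integrates the area under its
#' monotone (right-max) envelope. An 11-point interpolation is available
#' for comparability.
#'
#' @param scores Detection scores (one class, all images pooled).
#' @param tp Logical TP flag per detection (same order as `scores`).
#' @param n_gt Number of ground-truth instances of the class.
#' @param method `"area"` (all-point) or `"11point"`.
#' @return AP in `[0, 1]`; `NA` when `n_gt == 0` (class excluded from mAP).
#' @export
average_precision <- function(scores, tp, n_gt, method = c("area", "11point")) {
  method <- match.arg(method)
  if (n_gt == 0) return(NA_real_)
  if (!length(scores)) return(0)
  ord <- order(-scores, seq_along(scores))
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  rec <- cum_tp / n_gt
  prec <- cum_tp / (cum_tp + cum_fp)
  if (method == "11point") {
    return(mean(vapply(seq(0, 1, 0.1), function(r) {
      ok <- rec >= r
      if (any(ok)) max(prec[ok]) else 0
    }, numeric(1))))
  }
  # monotone envelope + exact area under the stepwise curve
  mrec <- c(0, rec, 1)
  mpre <- c(0, prec, 0)
  for (i in (length(mpre) - 1):1) mpre[i] <- max(mpre[i], mpre[i + 1])
  idx <- which(mrec[-1] != mrec[-length(mrec)])
  sum((mrec[idx + 1] - mrec[idx]) * mpre[idx + 1])
}

#' PR curve points for one class
#' @inheritParams average_precision
#' @return Data frame with `score`, `precision`, `recall`.
#' @export
pr_curve <- function(scores, tp, n_gt) {
  if (!length(scores))
    return(data.frame(score = numeric(0), precision = numeric(0),
                      recall = numeric(0)))
  ord <- order(-scores, seq_along(scores))
  cum_tp <- cumsum(tp[ord])
  cum_fp <- cumsum(!tp[ord])
  data.frame(score = scores[ord],
             precision = cum_tp / (cum_tp + cum_fp),
             recall = if (n_gt > 0) cum_tp / n_gt else rep(1, length(scores)))
}

#' Mean average precision
#' @param aps Per-class AP values (NA = class undefined, excluded).
#' @return Unweighted mean over the defined classes.
#' @export
mean_average_precision <- function(aps) {
  ok <- !is.na(aps)
  if (!any(ok)) stop("mAP undefined: no class has ground-truth instances")
  mean(aps[ok])
}

#' Frames per second from seconds-per-image
#' @param S Detection time for one image in seconds (S > 0).
#' @export
detection_fps <- function(S) {
  if (any(S <= 0)) stop("seconds per image must be positive")
  1 / S
}

#' Per-grade confusion matrix from detections
#'
#' Every ground truth is attributed the class of its highest-score
#' detection with IoU >= 0.5 regardless of that detection's class;
#' unmatched ground truths count to a `missed` column. Rows (actual
#' grades) are normalized to proportions.
#'
#' @param per_image List of `list(dets = ..., gts = ...)` pairs.
#' @param iou_threshold Localization threshold (default 0.5).
#' @param normalize Row-normalize to proportions.
#' @return 5 x 6 matrix (grades x grades + `missed`).
#' @export
confusion_matrix_detections <- function(per_image, iou_threshold = 0.5,
                                        normalize = TRUE) {
  grades <- kl_grades()
  cm <- matrix(0, 5, 6, dimnames = list(actual = grades,
                                        predicted = c(grades, "missed")))
  for (im in per_image) {
    gts <- im$gts; dets <- im$dets
    if (!NROW(gts)) next
    for (g in seq_len(nrow(gts))) {
      gb <- as.numeric(gts[g, c("x_min", "y_min", "x_max", "y_max")])
      row <- match(normalize_grade(gts$class[g]), grades)
      pred <- "missed"
      if (NROW(dets)) {
        ious <- box_iou_many(
          as.matrix(dets[, c("x_min", "y_min", "x_max", "y_max")]), gb)
        hit <- which(ious >= iou_threshold)
        if (length(hit)) {
          best <- hit[order(-dets$score[hit], hit)][1]
          pred <- normalize_grade(dets$class[best])
        }
      }
      cm[row, pred] <- cm[row, pred] + 1
    }
  }
  if (normalize) {
    rs <- rowSums(cm)
    nz <- rs > 0
    cm[nz, ] <- cm[nz, , drop = FALSE] / rs[nz]
  }
  cm
}

#' Evaluate a detector on a sample set
#'
#' Runs inference on every sample, pools detections per class and computes
#' per-class AP at the requested IoU thresholds, mAP, PR curves, the
#' per-grade confusion matrix and (optionally) the median detection FPS.
#'
#' @param model A `koa_detector`.
#' @param samples List of samples with `$image` and `$annotations`.
#' @param iou_thresholds AP thresholds (default 0.5 and 0.75).
#' @param fps Measure detection time (forward + NMS) per image.
#' @return An `eval_report` list.
#' @export
evaluate_detector <- function(model, samples,
                              iou_thresholds = c(0.5, 0.75), fps = TRUE) {
  grades <- kl_grades()
  per_image <- vector("list", length(samples))
  times <- numeric(length(samples))
  for (k in seq_along(samples)) {
    t0 <- proc.time()[["elapsed"]]
    dets <- detect_image(model, samples[[k]]$image)
    times[k] <- proc.time()[["elapsed"]] - t0
    gts <- samples[[k]]$annotations
    gts$class <- normalize_grade(gts$label)
    per_image[[k]] <- list(dets = dets, gts = gts)
  }
  ap <- matrix(NA_real_, length(grades), length(iou_thresholds),
               dimnames = list(grades, as.character(iou_thresholds)))
  curves <- list()
  for (ti in seq_along(iou_thresholds)) {
    thr <- iou_thresholds[ti]
    for (ci in seq_along(grades)) {
      cl <- grades[ci]
      scores <- numeric(0); tps <- logical(0); n_gt <- 0
      for (im in per_image) {
        dsub <- im$dets[im$dets$class == cl, , drop = FALSE]
        gsub <- im$gts[im$gts$class == cl, , drop = FALSE]
        n_gt <- n_gt + nrow(gsub)
        if (nrow(dsub)) {
          mo <- match_detections(dsub, gsub, thr)
          scores <- c(scores, dsub$score)
          tps <- c(tps, mo$tp)
        }
      }
      ap[ci, ti] <- average_precision(scores, tps, n_gt)
      curves[[paste0(cl, "@", thr)]] <- pr_curve(scores, tps, n_gt)
    }
  }
  map <- apply(ap, 2, mean_average_precision)
  report <- list(
    ap = ap, mAP = map,
    pr_curves = curves,
    confusion = confusion_matrix_detections(per_image),
    fps = if (fps) stats::median(detection_fps(pmax(times, 1e-6))) else NA,
    n_images = length(samples),
    per_image = per_image
  )
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Detection evaluation over", x$n_images, "images\n")
  print(round(x$ap, 4))
  cat("mAP:", paste(names(x$mAP), round(x$mAP, 4), sep = "=",
                    collapse = "  "), "\n")
  if (!is.na(x$fps)) cat("median FPS:", round(x$fps, 2), "\n")
  invisible(x)
}

#' Serialize an evaluation report to JSON
#' @param report An `eval_report`; @param path Destination file.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(
    ap = as.data.frame(report$ap),
    mAP = as.list(report$mAP),
    confusion = as.data.frame(report$confusion),
    fps = report$fps, n_images = report$n_images
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
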