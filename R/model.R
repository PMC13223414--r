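# Detector assembly: backbone + neck + head, plus single-image inference,
# checkpointing and a structural summary.

#' Detector configuration
#'
#' Bundles every architectural and inference setting of the detector. The
#' defaults describe the full-size model (B4-profile backbone, 256-channel
#' pyramid); [tiny_detector_config()] is the CPU-scale profile used by the
#' tests and examples.
#'
#' @param backbone A [backbone_config()].
#' @param neck_channels Uniform pyramid width.
#' @param num_classes Number of KL grades (default 5).
#' @param head_layers Interactive-extractor depth.
#' @param gn_groups Group-normalization groups in the head.
#' @param pafpn Keep the bottom-up aggregation path in the neck.
#' @param adaptive_fusion Learnable fusion weights in the neck.
#' @param task_aligned Apply the M/O alignment maps in the head.
#' @param align_mode `"geometric"` or `"product"` combination of P and M.
#' @param reg_loss `"eiou"` or `"l1"` box regression objective.
#' @param score_threshold Detection score floor (default 0.05).
#' @param nms_iou NMS IoU threshold (default 0.6).
#' @param max_detections Per-image detection cap.
#' @param tal_alpha,tal_beta,tal_topk Task-aligned assignment metric
#'   exponents (`score^alpha * IoU^beta`) and candidate count.
#' @param w_cls,w_reg Loss component weights.
#' @param focal A [cls_loss_config()].
#' @return A `detector_config` list.
#' @export
detector_config <- function(backbone = backbone_config(),
                            neck_channels = 256, num_classes = 5,
                            head_layers = 6, gn_groups = 32,
                            pafpn = TRUE, adaptive_fusion = TRUE,
                            task_aligned = TRUE, align_mode = "geometric",
                            reg_loss = c("eiou", "l1"),
                            score_threshold = 0.05, nms_iou = 0.6,
                            max_detections = 100,
                            tal_alpha = 1, tal_beta = 6, tal_topk = 13,
                            w_cls = 1, w_reg = 1,
                            focal = cls_loss_config()) {
  structure(list(
    backbone = backbone, neck_channels = neck_channels,
    num_classes = num_classes, head_layers = head_layers,
    gn_groups = gn_groups, pafpn = pafpn,
    adaptive_fusion = adaptive_fusion, task_aligned = task_aligned,
    align_mode = align_mode, reg_loss = match.arg(reg_loss),
    score_threshold = score_threshold, nms_iou = nms_iou,
    max_detections = max_detections,
    tal_alpha = tal_alpha, tal_beta = tal_beta, tal_topk = tal_topk,
    w_cls = w_cls, w_reg = w_reg, focal = focal,
    strides = c(8L, 16L, 32L, 64L, 128L)
  ), class = "detector_config")
}

#' Tiny CPU-scale detector profile
#'
#' Identical code path to the full profile with a width-0.25/depth-0.4
#' backbone, 32-channel pyramid and 64 px inputs.
#' @param ... Overrides passed to [detector_config()].
#' @export
tiny_detector_config <- function(...) {
  detector_config(backbone = tiny_backbone_config(),
                  neck_channels = 32, ...)
}

#' Build a detector
#'
#' @param cfg A [detector_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `koa_detector` with `$forward`, `$reg` (parameters) and `$cfg`.
#' @export
build_detector <- function(cfg = tiny_detector_config(), seed = 1) {
  reg <- param_registry()
  with_seed(seed, {
    backbone <- build_backbone(cfg$backbone, reg,
                               num_classes = cfg$num_classes)
    neck <- build_neck(reg, backbone$channels, cfg$neck_channels,
                       bottom_up = cfg$pafpn,
                       adaptive_fusion = cfg$adaptive_fusion)
    head <- build_head(reg, cfg$neck_channels,
                       num_classes = cfg$num_classes,
                       n_layers = cfg$head_layers,
                       gn_groups = cfg$gn_groups,
                       strides = cfg$strides,
                       alignment = cfg$task_aligned,
                       align_mode = cfg$align_mode)
  })
  model <- list(
    cfg = cfg, seed = seed, reg = reg,
    backbone = backbone, neck = neck, head = head,
    forward = function(image, training = FALSE) {
      feats <- backbone$forward(image, training)
      pyr <- neck$forward(feats$C4, feats$C5, feats$C6, training)
      levels <- lapply(seq_along(pyr), function(l)
        head$forward(pyr[[l]], l, training))
      names(levels) <- names(pyr)
      list(pyramid = pyr, levels = levels)
    }
  )
  class(model) <- "koa_detector"
  model
}

#' Number of trainable parameters
#' @param model A `koa_detector`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$reg$params, function(p) length(p$value), numeric(1)))
}

#' Structural summary of a detector
#' @param object A `koa_detector`; @param ... ignored.
#' @export
summary.koa_detector <- function(object, ...) {
  st <- object$cfg$backbone$stages
  cat("koadetect detector\n")
  cat("  backbone: width", object$cfg$backbone$width,
      "depth", object$cfg$backbone$depth,
      "| stage channels:", paste(st$channels_scaled, collapse = " "),
      "| repeats:", paste(st$repeats_scaled, collapse = " "), "\n")
  cat("  neck:", object$cfg$neck_channels, "channels,",
      if (object$cfg$pafpn) "PAFPN" else "FPN", "\n")
  cat("  head:", object$cfg$head_layers, "layers,",
      object$cfg$gn_groups, "GN groups, alignment",
      if (object$cfg$task_aligned) "on" else "off", "\n")
  cat("  classes:", object$cfg$num_classes,
      "| parameters:", n_parameters(object), "\n")
  invisible(object)
}

#' Detect lesions in a single grayscale image
#'
#' Runs the detector in evaluation mode, decodes every pyramid level,
#' applies the score floor and class-wise NMS.
#'
#' @param model A `koa_detector`.
#' @param image H x W matrix of 8-bit intensities.
#' @param score_threshold,nms_iou,max_detections Optional overrides of the
#'   config values.
#' @return Data frame `x_min,y_min,x_max,y_max,class,score`.
#' @export
detect_image <- function(model, image,
                         score_threshold = model$cfg$score_threshold,
                         nms_iou = model$cfg$nms_iou,
                         max_detections = model$cfg$max_detections) {
  out <- model$forward(image, training = FALSE)
  dets <- raw_detections(out, model$cfg$num_classes, score_threshold)
  if (nrow(dets) == 0) return(dets)
  dets <- nms(dets, nms_iou)
  utils::head(dets, max_detections)
}

# Flatten head outputs into a raw detection table (pre-NMS). Per level,
# only the `pre_nms_topk` highest-scoring (anchor, class) pairs above the
# score floor are kept — the usual dense-detector decoding cap.
raw_detections <- function(forward_out, num_classes, score_threshold,
                           pre_nms_topk = 100) {
  rows <- list()
  for (lv in forward_out$levels) {
    dec <- decode_level(lv)
    sc <- as.numeric(dec$scores)
    keep <- which(sc >= score_threshold)
    if (!length(keep)) next
    if (length(keep) > pre_nms_topk)
      keep <- keep[order(-sc[keep])[seq_len(pre_nms_topk)]]
    a <- ((keep - 1) %% nrow(dec$scores)) + 1
    cl <- ((keep - 1) %/% nrow(dec$scores)) + 1
    rows[[length(rows) + 1]] <- data.frame(
      x_min = dec$boxes[a, 1], y_min = dec$boxes[a, 2],
      x_max = dec$boxes[a, 3], y_max = dec$boxes[a, 4],
      class = kl_grades()[cl], score = sc[keep])
  }
  if (!length(rows))
    return(data.frame(x_min = numeric(0), y_min = numeric(0),
                      x_max = numeric(0), y_max = numeric(0),
                      class = character(0), score = numeric(0)))
  do.call(rbind, rows)
}

#' Save a detector checkpoint
#'
#' Self-describing archive: config, seed, parameter values and
#' normalization running statistics.
#' @param model A `koa_detector`; @param path Destination file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(
    cfg = model$cfg, seed = model$seed,
    params = lapply(model$reg$params, function(p) p$value),
    states = lapply(model$reg$states, function(s)
      list(mean = s$mean, var = s$var))
  ), path)
  invisible(path)
}

#' Load a detector checkpoint
#' @param path File written by [save_checkpoint()].
#' @return A rebuilt `koa_detector` with restored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_detector(ck$cfg, seed = ck$seed)
  for (nm in names(ck$params)) model$reg$params[[nm]]$value <- ck$params[[nm]]
  for (nm in names(ck$states)) {
    model$reg$states[[nm]]$mean <- ck$states[[nm]]$mean
    model$reg$states[[nm]]$var <- ck$states[[nm]]$var
  }
  model
}
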