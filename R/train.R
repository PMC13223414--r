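# Optimization: AdamW with norm-layer weight-decay exemption, linear warmup
# + step decay schedule, and the per-image (batch 1) training loop.

#' Training configuration
#'
#' Defaults follow the full-scale recipe: AdamW, initial learning rate
#' 2e-4, weight decay 1e-4 (normalization parameters exempt), step decay
#' x0.1 at epochs 8 and 11, linear warmup over 500 iterations at ratio
#' 0.001, 50 epochs, batch size 1.
#'
#' @param lr Base learning rate.
#' @param weight_decay Decoupled weight decay coefficient.
#' @param decay_epochs Epochs (1-based) at which the rate shrinks by 10x.
#' @param warmup_iters,warmup_ratio Linear warmup length and starting ratio.
#' @param epochs Total epochs.
#' @param batch_size Images per optimizer step (1, per-image updates).
#' @param grad_clip Optional global-norm gradient clip (NULL = off).
#' @param seed RNG seed for shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 2e-4, weight_decay = 1e-4,
                         decay_epochs = c(8, 11), warmup_iters = 500,
                         warmup_ratio = 0.001, epochs = 50, batch_size = 1,
                         grad_clip = NULL, seed = 1) {
  stopifnot(lr > 0, warmup_iters >= 0, !is.unsorted(decay_epochs))
  structure(list(lr = lr, weight_decay = weight_decay,
                 decay_epochs = decay_epochs, warmup_iters = warmup_iters,
                 warmup_ratio = warmup_ratio, epochs = epochs,
                 batch_size = batch_size, grad_clip = grad_clip,
                 seed = seed),
            class = "train_config")
}

#' Tiny-profile training configuration
#'
#' Scaled-down schedule for the 64 px phantom runs: 15 epochs at learning
#' rate 1e-3 with a 50-iteration warmup and decay at epochs 12 and 14
#' (the same warmup + two-step-decay shape as the full recipe, compressed).
#' @param lr,warmup_iters,decay_epochs,epochs Tiny-profile defaults.
#' @param ... Further overrides passed to [train_config()].
#' @export
tiny_train_config <- function(lr = 1e-3, warmup_iters = 50,
                              decay_epochs = c(12, 14), epochs = 15, ...) {
  train_config(lr = lr, warmup_iters = warmup_iters,
               decay_epochs = decay_epochs, epochs = epochs, ...)
}

#' Learning rate at a given iteration and epoch
#'
#' Linear ramp from `warmup_ratio * lr` to `lr` over the warmup iterations,
#' then step decay: x0.1 from each decay epoch onward.
#'
#' @param iteration Global 0-based iteration.
#' @param epoch 1-based epoch.
#' @param cfg A [train_config()].
#' @export
lr_schedule <- function(iteration, epoch, cfg = train_config()) {
  stopifnot(iteration >= 0)
  base <- cfg$lr * 0.1^sum(epoch >= cfg$decay_epochs)
  if (cfg$warmup_iters > 0 && iteration < cfg$warmup_iters) {
    frac <- iteration / cfg$warmup_iters
    return(base * (cfg$warmup_ratio + (1 - cfg$warmup_ratio) * frac))
  }
  base
}

adamw_state <- function() {
  st <- new.env(parent = emptyenv())
  st$t <- 0
  st$m <- list()
  st$v <- list()
  st
}

adamw_step <- function(reg, st, lr, weight_decay, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, grad_clip = NULL) {
  if (!is.null(grad_clip)) {
    sq <- 0
    for (p in reg$params) if (!is.null(p$grad)) sq <- sq + sum(p$grad^2)
    nrm <- sqrt(sq)
    scale <- if (nrm > grad_clip) grad_clip / nrm else 1
  } else scale <- 1
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(reg$params)) {
    p <- reg$params[[nm]]
    if (is.null(p$grad)) next
    g <- if (scale != 1) p$grad * scale else p$grad
    if (is.null(st$m[[nm]])) {
      st$m[[nm]] <- numeric(length(p$value))
      st$v[[nm]] <- numeric(length(p$value))
      # private copy so the C++ in-place update cannot touch a shared SEXP
      p$value <- p$value + 0
    }
    wd <- if (isTRUE(p$no_decay)) 0 else weight_decay
    cpp_adamw_update(p$value, g, st$m[[nm]], st$v[[nm]], lr, wd,
                     beta1, beta2, eps, bc1, bc2)
  }
  invisible(NULL)
}

# Flatten a forward pass into anchor tables used by assignment and the loss.
.flatten_levels <- function(out) {
  anchors <- list(); boxes <- list(); scores <- list(); level_of <- list()
  for (l in seq_along(out$levels)) {
    dec <- decode_level(out$levels[[l]])
    dec$anchors$level <- l
    anchors[[l]] <- dec$anchors
    boxes[[l]] <- dec$boxes
    scores[[l]] <- dec$scores
  }
  list(anchors = do.call(rbind, anchors), boxes = do.call(rbind, boxes),
       scores = do.call(rbind, scores),
       sizes = vapply(anchors, nrow, numeric(1)))
}

# One optimization step on a single sample; returns the logged scalars.
train_step <- function(model, sample, lr, opt, cfg, train_cfg) {
  out <- model$forward(sample$image, training = TRUE)
  fl <- .flatten_levels(out)
  gt <- sample$annotations
  if (!is.null(gt) && nrow(gt) > 0) {
    gt$class_idx <- match(normalize_grade(gt$label), kl_grades())
  } else gt <- NULL
  asn <- tal_assign(fl$anchors, fl$scores, fl$boxes, gt,
                    alpha = cfg$tal_alpha, beta = cfg$tal_beta,
                    topk = cfg$tal_topk)
  n_pos <- max(asn$n_pos, 1)
  pos <- which(asn$positive)
  reg_fn <- if (cfg$reg_loss == "eiou") eiou_loss else NULL

  # ---- loss values (for the log) ----
  gt_boxes_pos <- if (length(pos))
    as.matrix(gt[asn$gt_index[pos], c("x_min", "y_min", "x_max", "y_max")])
  else NULL
  if (cfg$reg_loss == "eiou") {
    lv <- total_detection_loss(fl$scores, asn$target,
                               fl$boxes[pos, , drop = FALSE], gt_boxes_pos,
                               cfg$focal, cfg$w_cls, cfg$w_reg)
  } else {
    cls <- focal_classification_loss(as.numeric(fl$scores),
                                     as.numeric(asn$target), cfg$focal)
    reg <- 0
    if (length(pos)) {
      per <- vapply(seq_along(pos), function(k) {
        a <- fl$anchors[pos[k], ]
        tgt <- encode_distances(gt_boxes_pos[k, ], c(a$x, a$y))
        dpred <- encode_distances(fl$boxes[pos[k], ], c(a$x, a$y))
        mean(abs(dpred - tgt)) / a$stride
      }, numeric(1))
      reg <- mean(per)
    }
    lv <- list(cls_loss = cls, reg_loss = reg,
               total = cfg$w_cls * cls + cfg$w_reg * reg)
  }
  if (!is.finite(lv$total))
    stop("non-finite loss at iteration ", opt$t + 1,
         " (cls=", lv$cls_loss, ", reg=", lv$reg_loss, ")")

  # ---- gradients w.r.t. the head outputs, injected into the tape ----
  grad_p <- .focal_grad_p(as.numeric(fl$scores), as.numeric(asn$target),
                          cfg$focal) * cfg$w_cls / n_pos
  grad_p <- matrix(grad_p, nrow(fl$scores), ncol(fl$scores))
  grad_d <- matrix(0, nrow(fl$boxes), 4)
  if (length(pos)) {
    n_reg <- length(pos)
    for (k in seq_along(pos)) {
      a <- fl$anchors[pos[k], ]
      if (cfg$reg_loss == "eiou") {
        gb <- box_loss_gradient(reg_fn, fl$boxes[pos[k], ], gt_boxes_pos[k, ])
        # box = (x - l, y - t, x + r, y + b)
        gd <- c(-gb[1], -gb[2], gb[3], gb[4])
      } else {
        tgt <- encode_distances(gt_boxes_pos[k, ], c(a$x, a$y))
        dpred <- encode_distances(fl$boxes[pos[k], ], c(a$x, a$y))
        gd <- sign(dpred - tgt) / (4 * a$stride)
      }
      grad_d[pos[k], ] <- gd * cfg$w_reg / n_reg
    }
  }
  ad_zero_grad(model$reg$params)
  offsets <- c(0, cumsum(fl$sizes))
  outputs <- list(); grads <- list()
  for (l in seq_along(out$levels)) {
    lv_out <- out$levels[[l]]
    d <- dim(ad_value(lv_out$P_align))
    idx <- (offsets[l] + 1):offsets[l + 1]
    ga <- array(0, d)
    ap <- fl$anchors[idx, ]
    for (cl in seq_len(d[3])) ga[cbind(ap$i, ap$j, cl)] <- grad_p[idx, cl]
    outputs[[length(outputs) + 1]] <- lv_out$P_align
    grads[[length(grads) + 1]] <- ga
    if (any(grad_d[idx, ] != 0)) {
      gd_arr <- array(0, dim(ad_value(lv_out$dist_align)))
      for (c4 in 1:4) gd_arr[cbind(ap$i, ap$j, c4)] <- grad_d[idx, c4]
      outputs[[length(outputs) + 1]] <- lv_out$dist_align
      grads[[length(grads) + 1]] <- gd_arr
    }
  }
  ad_backward(outputs, grads)
  adamw_step(model$reg, opt, lr, train_cfg$weight_decay,
             grad_clip = train_cfg$grad_clip)
  list(cls_loss = lv$cls_loss, reg_loss = lv$reg_loss, total = lv$total,
       n_pos = asn$n_pos)
}

#' Train a detector
#'
#' Per-image AdamW optimization with the warmup + step-decay schedule;
#' normalization-layer parameters are exempt from weight decay. Emits a
#' line-per-iteration log of the loss components.
#'
#' @param model A `koa_detector` from [build_detector()].
#' @param samples List of training samples (`$image`, `$annotations`).
#' @param train_cfg A [train_config()].
#' @param eval_samples Optional held-out samples; when given, mAP@0.5 is
#'   recorded after every epoch.
#' @param checkpoint Optional path for the final checkpoint.
#' @param verbose Print epoch summaries.
#' @return List with the trained `model`, iteration `log` data frame and
#'   per-epoch `history`.
#' @export
train_detector <- function(model, samples, train_cfg = tiny_train_config(),
                           eval_samples = NULL, checkpoint = NULL,
                           verbose = FALSE) {
  opt <- adamw_state()
  logs <- vector("list", train_cfg$epochs * length(samples))
  history <- list()
  it <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- with_seed(train_cfg$seed + epoch,
                     sample.int(length(samples)))
    for (si in ord) {
      lr <- lr_schedule(it, epoch, train_cfg)
      res <- train_step(model, samples[[si]], lr, opt, model$cfg, train_cfg)
      it <- it + 1L
      logs[[it]] <- data.frame(iteration = it, epoch = epoch, lr = lr,
                               cls_loss = res$cls_loss,
                               reg_loss = res$reg_loss,
                               total_loss = res$total, n_pos = res$n_pos)
    }
    ep_log <- do.call(rbind, logs[(it - length(samples) + 1):it])
    hist_row <- data.frame(epoch = epoch,
                           mean_total_loss = mean(ep_log$total_loss),
                           mAP50 = NA_real_)
    if (!is.null(eval_samples)) {
      rep <- evaluate_detector(model, eval_samples,
                               iou_thresholds = 0.5, fps = FALSE)
      hist_row$mAP50 <- rep$mAP["0.5"]
    }
    history[[epoch]] <- hist_row
    if (verbose)
      message(sprintf("epoch %d | loss %.4f | mAP50 %s", epoch,
                      hist_row$mean_total_loss,
                      format(hist_row$mAP50, digits = 4)))
  }
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
  list(model = model, log = do.call(rbind, logs[seq_len(it)]),
       history = do.call(rbind, history))
}
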