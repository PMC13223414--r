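# Task-aligned detection head.
#
# A stack of N (default 6) 3x3 convolutions with 32-group normalization and
# ReLU computes task-interaction features X_k^inter shared by classification
# and localization. Each task then applies layer attention: a two-layer FC
# on the pooled concatenated features yields sigmoid weights omega in (0,1)^N
# that rescale each interaction layer before a 1x1 reduction and the task's
# prediction convolution. Classification goes through a sigmoid to dense
# scores P; localization emits four per-boundary distances (exponential
# mapping scaled by a per-level learnable factor and the level stride).
# Two alignment maps are learned from the interaction stack: a spatial
# probability map M in (0,1)^(HxW) that refines P (geometric mean
# sqrt(P*M)), and an 8-channel offset map O whose (delta_i, delta_j) pairs
# re-sample each of the four boundary distances by bilinear interpolation.
# Head weights are shared across pyramid levels.

#' Build the task-aligned head
#'
#' @param reg Parameter registry.
#' @param channels Pyramid channel width (input and tower width).
#' @param num_classes Number of object classes (default 5 KL grades).
#' @param n_layers Interactive-extractor depth (default 6).
#' @param gn_groups Group-normalization group count (default 32).
#' @param n_levels Number of pyramid levels served (per-level distance scales).
#' @param strides Level strides in pixels.
#' @param alignment Apply the M/O alignment maps; `FALSE` reduces the head
#'   to a plain decoupled head (M = 1, O = 0).
#' @param align_mode `"geometric"` for `sqrt(P*M)` or `"product"` for `P*M`.
#' @param prior_prob Initial positive prior of the classification logits.
#' @return Head object; `$forward(level_node, level_index, training)` returns
#'   the per-level maps.
#' @export
build_head <- function(reg, channels, num_classes = 5, n_layers = 6,
                       gn_groups = 32, n_levels = 5,
                       strides = c(8, 16, 32, 64, 128),
                       alignment = TRUE, align_mode = "geometric",
                       prior_prob = 0.01) {
  if (channels %% gn_groups != 0)
    stop("head channels (", channels, ") must be divisible by the ",
         "group-normalization group count (", gn_groups, ")")
  inter <- lapply(seq_len(n_layers), function(k)
    layer_conv(reg, paste0("head.inter", k), channels, channels, k = 3,
               norm = "gn", act = "relu", groups = gn_groups))
  catc <- n_layers * channels
  att_hidden <- max(8L, catc %/% 4L)
  att <- lapply(c("cls", "loc"), function(task) list(
    fc1 = layer_fc(reg, paste0("head.att.", task, ".fc1"), catc, att_hidden),
    fc2 = layer_fc(reg, paste0("head.att.", task, ".fc2"), att_hidden,
                   n_layers)))
  names(att) <- c("cls", "loc")
  red_cls <- layer_conv(reg, "head.cls.reduce", catc, channels, k = 1,
                        bias = TRUE)
  red_loc <- layer_conv(reg, "head.loc.reduce", catc, channels, k = 1,
                        bias = TRUE)
  cls_pred <- layer_conv(reg, "head.cls.pred", channels, num_classes, k = 3,
                         bias = TRUE,
                         bias_init = -log((1 - prior_prob) / prior_prob))
  loc_pred <- layer_conv(reg, "head.loc.pred", channels, 4, k = 3, bias = TRUE)
  mid <- max(8L, channels %/% 4L)
  m_stack <- list(
    layer_conv(reg, "head.M.1", catc, mid, k = 1, bias = TRUE, act = "relu"),
    layer_conv(reg, "head.M.2", mid, 1, k = 1, bias = TRUE))
  o_stack <- list(
    layer_conv(reg, "head.O.1", catc, mid, k = 1, bias = TRUE, act = "relu"),
    layer_conv(reg, "head.O.2", mid, 8, k = 1, bias = TRUE, w_scale = 0))
  dist_scale <- lapply(seq_len(n_levels), function(l)
    new_param(reg, paste0("head.dist_scale", l), 1, no_decay = TRUE))

  omega_of <- function(task, x_vec) {
    ad_sigmoid(att[[task]]$fc2$fn(ad_relu(att[[task]]$fc1$fn(x_vec))))
  }
  # X_k^task = omega_k * X_k^inter, applied as a blockwise channel gate on
  # the already-concatenated interaction stack (exactly equivalent to
  # scaling each layer then concatenating)
  task_feats <- function(cat_inter, omega) {
    ad_scale_channels(cat_inter, ad_rep_gate(omega, channels))
  }

  obj <- list(
    channels = channels, num_classes = num_classes, n_layers = n_layers,
    gn_groups = gn_groups, strides = strides, alignment = alignment,
    forward = function(x, level, training = FALSE) {
      inter_maps <- list()
      y <- x
      for (k in seq_len(n_layers)) {
        y <- inter[[k]]$fn(y, training)
        inter_maps[[k]] <- y
      }
      cat_inter <- ad_concat_c(inter_maps)
      x_vec <- ad_gap(cat_inter)
      om_cls <- omega_of("cls", x_vec)
      om_loc <- omega_of("loc", x_vec)
      p_raw <- ad_sigmoid(cls_pred$fn(
        ad_relu(red_cls$fn(task_feats(cat_inter, om_cls), training)),
        training))
      z_loc <- loc_pred$fn(
        ad_relu(red_loc$fn(task_feats(cat_inter, om_loc), training)),
        training)
      dist <- ad_scalar_mul(
        ad_exp(ad_clamp(ad_scalar_mul(z_loc, dist_scale[[level]]), -8, 8)),
        strides[level])
      if (alignment) {
        m_map <- ad_sigmoid(m_stack[[2]]$fn(m_stack[[1]]$fn(cat_inter,
                                                            training),
                                            training))
        o_map <- o_stack[[2]]$fn(o_stack[[1]]$fn(cat_inter, training),
                                 training)
        p_align <- if (align_mode == "product")
          ad_broadcast_mul(p_raw, m_map)
        else
          ad_sqrt(ad_broadcast_mul(p_raw, m_map))
        dist_align <- ad_offset_sample(dist, o_map)
      } else {
        m_map <- NULL; o_map <- NULL
        p_align <- p_raw
        dist_align <- dist
      }
      list(P = p_raw, P_align = p_align, dist = dist,
           dist_align = dist_align, M = m_map, O = o_map,
           omega_cls = om_cls, omega_loc = om_loc,
           inter = inter_maps, stride = strides[level])
    }
  )
  class(obj) <- "koa_head"
  obj
}

#' Decode a head level's aligned outputs into flat detections
#'
#' @param level_out One element of a head forward pass.
#' @return Data frame with anchors, per-class scores and decoded boxes.
#' @export
decode_level <- function(level_out) {
  dist <- ad_value(level_out$dist_align)
  p <- ad_value(level_out$P_align)
  d <- dim(dist)
  ap <- anchor_points(d[1], d[2], level_out$stride)
  flat_idx <- cbind(ap$i, ap$j)
  boxes <- cbind(ap$x - dist[cbind(flat_idx, 1)],
                 ap$y - dist[cbind(flat_idx, 2)],
                 ap$x + dist[cbind(flat_idx, 3)],
                 ap$y + dist[cbind(flat_idx, 4)])
  colnames(boxes) <- c("x_min", "y_min", "x_max", "y_max")
  scores <- matrix(0, nrow(ap), dim(p)[3])
  for (cl in seq_len(dim(p)[3])) scores[, cl] <- p[cbind(flat_idx, cl)]
  list(anchors = ap, boxes = boxes, scores = scores)
}
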