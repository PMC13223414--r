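# Path Aggregation Feature Pyramid (PAFPN) neck.
#
# The three backbone taps are projected to a uniform channel width by 1x1
# laterals, fused top-down (coarse-to-fine, nearest-neighbour 2x upsampling)
# and then aggregated bottom-up with stride-2 3x3 convolutions; P6 and P7
# come from two further stride-2 convolutions off P5. Every fusion addition
# optionally carries learnable softmax-normalized weights ("adaptive
# fusion"); a config flag drops the bottom-up stage, reducing the neck to a
# plain FPN for the ablation harness.

#' Build the neck
#'
#' @param reg Parameter registry.
#' @param in_channels Channel counts of the C4/C5/C6 inputs.
#' @param out_channels Uniform pyramid width (default 256).
#' @param bottom_up Keep the bottom-up aggregation path (PAFPN); `FALSE`
#'   gives a plain FPN.
#' @param adaptive_fusion Learn softmax-normalized scalar weights on each
#'   two-map addition instead of a plain sum.
#' @return Neck object with `$forward(C4, C5, C6, training)` returning the
#'   five pyramid level nodes (strides 8, 16, 32, 64, 128).
#' @export
build_neck <- function(reg, in_channels, out_channels = 256,
                       bottom_up = TRUE, adaptive_fusion = TRUE) {
  lat <- lapply(1:3, function(k)
    layer_conv(reg, paste0("neck.lateral", k), in_channels[k], out_channels,
               k = 1, bias = FALSE))
  fuse_w <- function(name) {
    if (adaptive_fusion) new_param(reg, name, c(0, 0), no_decay = TRUE)
    else NULL
  }
  td_w <- list(fuse_w("neck.td.w4"), fuse_w("neck.td.w3"))
  down <- list(
    layer_conv(reg, "neck.down4", out_channels, out_channels, k = 3,
               stride = 2, bias = TRUE),
    layer_conv(reg, "neck.down5", out_channels, out_channels, k = 3,
               stride = 2, bias = TRUE))
  bu_w <- list(fuse_w("neck.bu.w4"), fuse_w("neck.bu.w5"))
  p6_conv <- layer_conv(reg, "neck.p6", out_channels, out_channels, k = 3,
                        stride = 2, bias = TRUE)
  p7_conv <- layer_conv(reg, "neck.p7", out_channels, out_channels, k = 3,
                        stride = 2, bias = TRUE)

  fuse <- function(a, b, w) {
    # a, b: same-shape maps; w: optional length-2 fusion logit param.
    # Softmax weights are scaled by 2 so the zero-logit init reproduces the
    # plain sum exactly.
    if (is.null(w)) return(ad_add(a, b))
    sm <- .softmax_node(w)
    ad_add(ad_scalar_mul(ad_scalar_mul(a, ad_vec_slice(sm, 1)), 2),
           ad_scalar_mul(ad_scalar_mul(b, ad_vec_slice(sm, 2)), 2))
  }

  obj <- list(
    out_channels = out_channels, bottom_up = bottom_up,
    strides = c(8L, 16L, 32L, 64L, 128L),
    forward = function(C4, C5, C6, training = FALSE) {
      l3 <- lat[[1]]$fn(C4, training)
      l4 <- lat[[2]]$fn(C5, training)
      l5 <- lat[[3]]$fn(C6, training)
      # top-down fusion, coarse to fine
      f5 <- l5
      f4 <- fuse(l4, ad_upsample_nearest(f5, dim(l4$value)[1],
                                         dim(l4$value)[2]), td_w[[1]])
      f3 <- fuse(l3, ad_upsample_nearest(f4, dim(l3$value)[1],
                                         dim(l3$value)[2]), td_w[[2]])
      if (bottom_up) {
        p3 <- f3
        p4 <- ad_relu(fuse(down[[1]]$fn(p3, training), f4, bu_w[[1]]))
        p5 <- ad_relu(fuse(down[[2]]$fn(p4, training), f5, bu_w[[2]]))
      } else {
        p3 <- f3; p4 <- f4; p5 <- f5
      }
      p6 <- ad_relu(p6_conv$fn(p5, training))
      p7 <- ad_relu(p7_conv$fn(p6, training))
      list(P3 = p3, P4 = p4, P5 = p5, P6 = p6, P7 = p7)
    }
  )
  class(obj) <- "koa_neck"
  obj
}

# softmax over a small vector node (used for the two fusion weights)
.softmax_node <- function(x) {
  v <- as.numeric(x$value)
  e <- exp(v - max(v))
  s <- e / sum(e)
  out <- ad_new_node(s, list(x))
  out$backward <- function(g) {
    g <- as.numeric(g)
    .ad_accum(x, s * (g - sum(g * s)))
  }
  out
}
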