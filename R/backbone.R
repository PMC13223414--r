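# EfficientNet-style backbone with compound scaling. The base profile is the
# canonical B0 stage table; a width/depth multiplier pair scales channels
# (rounded to a multiple of 8) and per-stage repeats (ceiling). The defaults
# reproduce the B4 profile (width 1.4, depth 1.8, resolution 380); a "tiny"
# profile (width 0.25, depth 0.4, resolution 64) runs the identical code path
# at CPU-test scale.

.b0_stages <- function() {
  data.frame(
    operator = c("mbconv1", "mbconv6", "mbconv6", "mbconv6", "mbconv6",
                 "mbconv6", "mbconv6"),
    kernel = c(3, 3, 5, 3, 5, 5, 3),
    stride = c(1, 2, 2, 2, 1, 2, 1),
    expansion = c(1, 6, 6, 6, 6, 6, 6),
    channels = c(16, 24, 40, 80, 112, 192, 320),
    repeats = c(1, 2, 2, 3, 3, 4, 1)
  )
}

#' Round a scaled channel count to a multiple of the divisor
#'
#' Standard compound-scaling filter rounding: nearest multiple of `divisor`,
#' never dropping below 90% of the scaled value.
#' @param channels Base channel count.
#' @param width Width multiplier.
#' @param divisor Rounding divisor (default 8).
#' @export
round_filters <- function(channels, width, divisor = 8) {
  f <- channels * width
  new_f <- max(divisor, (floor(f + divisor / 2) %/% divisor) * divisor)
  if (new_f < 0.9 * f) new_f <- new_f + divisor
  as.integer(new_f)
}

#' Round a scaled repeat count
#' @param repeats Base repeats; @param depth Depth multiplier.
#' @export
round_repeats <- function(repeats, depth) as.integer(ceiling(repeats * depth))

#' Backbone configuration
#'
#' @param width,depth Compound-scaling multipliers (defaults 1.4 and 1.8,
#'   the B4 profile).
#' @param resolution Nominal input resolution.
#' @param se_ratio Squeeze-and-excitation bottleneck ratio.
#' @param divisor Channel rounding divisor.
#' @param drop_rate Stochastic-depth rate inside MBConv blocks.
#' @return A `backbone_config` list including the scaled stage table.
#' @export
backbone_config <- function(width = 1.4, depth = 1.8, resolution = 380,
                            se_ratio = 0.25, divisor = 8, drop_rate = 0) {
  stopifnot(width > 0, depth > 0)
  st <- .b0_stages()
  st$channels_scaled <- vapply(st$channels, round_filters, integer(1),
                               width = width, divisor = divisor)
  st$repeats_scaled <- vapply(st$repeats, round_repeats, integer(1),
                              depth = depth)
  structure(list(
    width = width, depth = depth, resolution = resolution,
    se_ratio = se_ratio, divisor = divisor, drop_rate = drop_rate,
    stem_channels = round_filters(32, width, divisor),
    head_channels = round_filters(1280, width, divisor),
    stages = st
  ), class = "backbone_config")
}

#' Tiny backbone profile for CPU-scale runs
#' @inheritParams backbone_config
#' @export
tiny_backbone_config <- function(width = 0.25, depth = 0.4, resolution = 64,
                                 drop_rate = 0) {
  backbone_config(width = width, depth = depth, resolution = resolution,
                  drop_rate = drop_rate)
}

#' Build the backbone
#'
#' Nine phases: a stride-2 stem convolution, seven MBConv stage groups, and
#' a 1x1 convolution + pooling + fully connected classification head (kept
#' for structural completeness; the detector taps the stride-8/16/32 stage
#' outputs C4, C5, C6 instead).
#'
#' @param cfg A [backbone_config()].
#' @param reg Parameter registry (created if missing).
#' @param num_classes Width of the optional classification head.
#' @return A backbone object with `$forward(image, training)` returning the
#'   C4/C5/C6 feature nodes and `$channels` the per-tap channel counts.
#' @export
build_backbone <- function(cfg = backbone_config(), reg = param_registry(),
                           num_classes = 5) {
  st <- cfg$stages
  stem <- layer_conv(reg, "backbone.stem", 3, cfg$stem_channels, k = 3,
                     stride = 2, norm = "bn", act = "swish")
  blocks <- list()
  cin <- cfg$stem_channels
  for (s in seq_len(nrow(st))) {
    for (r in seq_len(st$repeats_scaled[s])) {
      blocks[[length(blocks) + 1]] <- list(
        stage = s,
        layer = layer_mbconv(reg, sprintf("backbone.s%d.b%d", s, r),
                             cin, st$channels_scaled[s],
                             k = st$kernel[s],
                             stride = if (r == 1) st$stride[s] else 1,
                             expansion = st$expansion[s],
                             se_ratio = cfg$se_ratio,
                             drop_rate = cfg$drop_rate))
      cin <- st$channels_scaled[s]
    }
  }
  head_conv <- layer_conv(reg, "backbone.head", cin, cfg$head_channels,
                          k = 1, norm = "bn", act = "swish")
  head_fc <- layer_fc(reg, "backbone.fc", cfg$head_channels, num_classes)
  taps <- c(3, 5, 7)  # stage groups at strides 8, 16, 32
  obj <- list(
    cfg = cfg, reg = reg,
    channels = st$channels_scaled[taps],
    strides = c(8L, 16L, 32L),
    forward = function(image, training = FALSE) {
      x <- .image_to_input(image)
      y <- stem$fn(x, training)
      feats <- list()
      for (b in blocks) {
        y <- b$layer$fn(y, training)
        feats[[b$stage]] <- y
      }
      list(C4 = feats[[taps[1]]], C5 = feats[[taps[2]]],
           C6 = feats[[taps[3]]])
    },
    classify = function(image, training = FALSE) {
      x <- .image_to_input(image)
      y <- stem$fn(x, training)
      for (b in blocks) y <- b$layer$fn(y, training)
      head_fc$fn(ad_gap(head_conv$fn(y, training)))
    }
  )
  class(obj) <- "koa_backbone"
  obj
}

# Replicate a grayscale raster to the 3-channel stem input and scale to
# roughly unit range.
.image_to_input <- function(image) {
  if (inherits(image, "ad_node")) return(image)
  m <- as.matrix(image)
  if (min(dim(m)) < 32)
    stop("image must be at least 32 px in both dimensions")
  x <- array(rep(as.numeric(m) / 255, 3), c(nrow(m), ncol(m), 3))
  ad_const(x)
}

#' Run the backbone on a grayscale image
#' @param backbone From [build_backbone()].
#' @param image H x W matrix of 8-bit intensities.
#' @param training Training mode flag.
#' @return List of C4, C5, C6 feature nodes (strides 8, 16, 32).
#' @export
backbone_forward <- function(backbone, image, training = FALSE) {
  backbone$forward(image, training)
}
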