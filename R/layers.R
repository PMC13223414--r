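# Layer constructors. A layer is a list holding its parameter nodes plus a
# forward closure `fn(x, training)`; all parameters are registered in a
# shared registry so the optimizer and checkpointing can reach them.

#' Create a parameter registry
#'
#' Holds every trainable parameter node and the running statistics of the
#' normalization layers for one model instance.
#' @return An environment with `params` and `states` lists.
#' @keywords internal
param_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$params <- list()
  reg$states <- list()
  reg
}

new_param <- function(reg, name, value, no_decay = FALSE) {
  if (!is.null(reg$params[[name]]))
    stop("duplicate parameter name: ", name)
  p <- ad_param(value, name = name)
  p$no_decay <- no_decay
  reg$params[[name]] <- p
  p
}

new_bn_state <- function(reg, name, C) {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(C)
  st$var <- rep(1, C)
  reg$states[[name]] <- st
  st
}

.he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

#' Convolution layer with optional normalization and activation
#'
#' @param reg Parameter registry.
#' @param name Layer name (prefix for its parameters).
#' @param cin,cout Input/output channels.
#' @param k Kernel size (odd).
#' @param stride Stride.
#' @param norm One of "bn", "gn", "none".
#' @param act One of "swish", "relu", "sigmoid", "none".
#' @param groups Group count for "gn".
#' @param bias Add a bias term (only when `norm == "none"`).
#' @param w_scale Multiplier on the weight init (0 gives a zero-init layer).
#' @param bias_init Initial bias value.
#' @return Layer list with `$fn(x, training)`.
#' @keywords internal
layer_conv <- function(reg, name, cin, cout, k = 3, stride = 1,
                       norm = "none", act = "none", groups = 32,
                       bias = (norm == "none"), w_scale = 1,
                       bias_init = 0) {
  w <- new_param(reg, paste0(name, ".w"), .he_init(k, k, cin, cout) * w_scale)
  b <- if (bias)
    new_param(reg, paste0(name, ".b"), rep(bias_init, cout), no_decay = TRUE)
  gamma <- beta <- NULL
  st <- NULL
  if (norm == "bn") {
    gamma <- new_param(reg, paste0(name, ".bn.g"), rep(1, cout), no_decay = TRUE)
    beta <- new_param(reg, paste0(name, ".bn.b"), rep(0, cout), no_decay = TRUE)
    st <- new_bn_state(reg, paste0(name, ".bn"), cout)
  } else if (norm == "gn") {
    if (cout %% groups != 0)
      stop("group normalization: ", cout, " channels not divisible by ",
           groups, " groups")
    gamma <- new_param(reg, paste0(name, ".gn.g"), rep(1, cout), no_decay = TRUE)
    beta <- new_param(reg, paste0(name, ".gn.b"), rep(0, cout), no_decay = TRUE)
  }
  act_fn <- switch(act, swish = ad_swish, relu = ad_relu,
                   sigmoid = ad_sigmoid, none = identity)
  list(
    name = name, cout = cout,
    fn = function(x, training = FALSE) {
      y <- ad_conv2d(x, w, b, stride = stride)
      if (norm == "bn")
        y <- ad_batchnorm(y, gamma, beta, st, training)
      else if (norm == "gn")
        y <- ad_groupnorm(y, gamma, beta, groups)
      act_fn(y)
    }
  )
}

#' Squeeze-and-excitation channel attention block
#'
#' Global average pool, bottleneck FC with ReLU, restoring FC with sigmoid,
#' then channelwise rescaling; the excitation gates therefore lie in (0, 1)
#' and the output never exceeds a nonnegative input elementwise.
#'
#' @param reg Parameter registry; @param name Layer name.
#' @param c_in Channel count of the gated map.
#' @param se_ratio Bottleneck ratio (bottleneck width
#'   `max(1, round(c_base * se_ratio))`).
#' @param c_base Reference width for the bottleneck (defaults to `c_in`).
#' @return Layer list; `$fn` returns the rescaled map, `$gates(x)` the
#'   excitation vector.
#' @export
layer_se <- function(reg, name, c_in, se_ratio = 0.25, c_base = c_in) {
  c_mid <- max(1L, round(c_base * se_ratio))
  w1 <- new_param(reg, paste0(name, ".fc1.w"),
                  matrix(stats::rnorm(c_in * c_mid, sd = sqrt(2 / c_in)),
                         c_in, c_mid))
  b1 <- new_param(reg, paste0(name, ".fc1.b"), numeric(c_mid), no_decay = TRUE)
  w2 <- new_param(reg, paste0(name, ".fc2.w"),
                  matrix(stats::rnorm(c_mid * c_in, sd = sqrt(2 / c_mid)),
                         c_mid, c_in))
  b2 <- new_param(reg, paste0(name, ".fc2.b"), numeric(c_in), no_decay = TRUE)
  gate <- function(x) {
    sq <- ad_gap(x)
    ad_sigmoid(ad_fc(ad_relu(ad_fc(sq, w1, b1)), w2, b2))
  }
  list(
    name = name,
    gates = function(x) gate(x),
    fn = function(x, training = FALSE) ad_scale_channels(x, gate(x))
  )
}

#' Depthwise-separable convolution layer
#'
#' Per-channel spatial convolution followed by 1x1 cross-channel mixing;
#' parameter count `C k^2 + C C_out` versus `C C_out k^2` for a dense kernel.
#'
#' @inheritParams layer_conv
#' @export
layer_dwseparable <- function(reg, name, cin, cout, k = 3, stride = 1) {
  wd <- new_param(reg, paste0(name, ".dw.w"),
                  array(stats::rnorm(k * k * cin, sd = sqrt(2 / (k * k))),
                        c(k, k, cin)))
  pw <- layer_conv(reg, paste0(name, ".pw"), cin, cout, k = 1, bias = TRUE)
  list(
    name = name, cout = cout,
    fn = function(x, training = FALSE)
      pw$fn(ad_dwconv2d(x, wd, stride = stride), training)
  )
}

#' Parameter count of a k x k convolution, dense vs depthwise-separable
#' @param cin,cout Channels; @param k kernel size.
#' @param separable Count the depthwise + pointwise factorization.
#' @param bias Include bias terms.
#' @return Integer parameter count.
#' @export
conv_param_count <- function(cin, cout, k, separable = FALSE, bias = FALSE) {
  n <- if (separable) cin * k^2 + cin * cout else cin * cout * k^2
  if (bias) n <- n + cout + if (separable) 0 else 0
  n
}

#' Mobile inverted bottleneck (MBConv) block
#'
#' Expansion 1x1 conv (BN + swish), depthwise k x k conv (BN + swish),
#' squeeze-and-excitation gate, 1x1 projection (BN, linear), stochastic
#' depth dropout on the branch, and a residual connection when the stride
#' is 1 and the channel counts match.
#'
#' @inheritParams layer_conv
#' @param expansion Expansion factor (1 or 6).
#' @param se_ratio SE bottleneck ratio relative to the block input width.
#' @param drop_rate Stochastic-depth drop probability during training.
#' @export
layer_mbconv <- function(reg, name, cin, cout, k = 3, stride = 1,
                         expansion = 6, se_ratio = 0.25, drop_rate = 0) {
  cexp <- cin * expansion
  expand <- if (expansion != 1)
    layer_conv(reg, paste0(name, ".expand"), cin, cexp, k = 1,
               norm = "bn", act = "swish")
  wd <- new_param(reg, paste0(name, ".dw.w"),
                  array(stats::rnorm(k * k * cexp, sd = sqrt(2 / (k * k))),
                        c(k, k, cexp)))
  dwg <- new_param(reg, paste0(name, ".dw.bn.g"), rep(1, cexp), no_decay = TRUE)
  dwb <- new_param(reg, paste0(name, ".dw.bn.b"), rep(0, cexp), no_decay = TRUE)
  dwst <- new_bn_state(reg, paste0(name, ".dw.bn"), cexp)
  se <- layer_se(reg, paste0(name, ".se"), cexp, se_ratio, c_base = cin)
  project <- layer_conv(reg, paste0(name, ".project"), cexp, cout, k = 1,
                        norm = "bn", act = "none")
  use_res <- (stride == 1 && cin == cout)
  list(
    name = name, cout = cout,
    fn = function(x, training = FALSE) {
      y <- x
      if (expansion != 1) y <- expand$fn(y, training)
      y <- ad_dwconv2d(y, wd, stride = stride)
      y <- ad_swish(ad_batchnorm(y, dwg, dwb, dwst, training))
      y <- se$fn(y, training)
      y <- project$fn(y, training)
      if (use_res) {
        if (training && drop_rate > 0) {
          if (stats::runif(1) < drop_rate) return(x)
          y <- ad_scalar_mul(y, 1 / (1 - drop_rate))
        }
        y <- ad_add(y, x)
      }
      y
    }
  )
}

#' Fully connected layer
#' @inheritParams layer_conv
#' @param n_in,n_out Input/output widths.
#' @keywords internal
layer_fc <- function(reg, name, n_in, n_out, w_scale = 1) {
  w <- new_param(reg, paste0(name, ".w"),
                 matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)) *
                          w_scale, n_in, n_out))
  b <- new_param(reg, paste0(name, ".b"), numeric(n_out), no_decay = TRUE)
  list(name = name,
       fn = function(x) ad_fc(x, w, b))
}
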