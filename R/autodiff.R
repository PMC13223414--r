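# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Every value on the tape is an `ad_node` environment holding the forward
# value, an accumulated gradient, its parent nodes and a backward closure.
# Nodes get a monotonically increasing id at creation, so reverse-id order
# is a valid topological order for backpropagation (single-threaded build).

.ad_state <- new.env(parent = emptyenv())
.ad_state$counter <- 0
.ad_state$bw_token <- 0L

ad_new_node <- function(value, parents = list(), backward = NULL,
                        requires = FALSE) {
  # Force the promises BEFORE taking an id: with lazy evaluation a nested
  # op call would otherwise build its parent nodes after this node has
  # claimed its id, breaking the reverse-id topological order backward
  # relies on.
  force(parents)
  force(value)
  .ad_state$counter <- .ad_state$counter + 1
  node <- new.env(parent = emptyenv())
  node$id <- .ad_state$counter
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$requires <- requires || any(vapply(parents, function(p) p$requires,
                                          logical(1)))
  class(node) <- "ad_node"
  node
}

#' Create a trainable parameter node
#'
#' @param value Numeric array/vector of initial values.
#' @param name Optional label used in diagnostics.
#' @return An `ad_node` participating in gradient accumulation.
#' @keywords internal
ad_param <- function(value, name = NULL) {
  node <- ad_new_node(value, requires = TRUE)
  node$is_param <- TRUE
  node$name <- name
  node
}

ad_const <- function(value) ad_new_node(value)

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

.ad_accum <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Backpropagate from one or more output nodes
#'
#' Seeds the given output nodes with the supplied gradients and accumulates
#' gradients into every ancestor parameter node.
#' @keywords internal
ad_backward <- function(outputs, grads) {
  if (inherits(outputs, "ad_node")) {
    outputs <- list(outputs)
    grads <- list(grads)
  }
  # Visited-marking uses a per-call token stamped on the node environments:
  # string-keyed lookups would intern a fresh id string per node into R's
  # permanent string cache, growing memory and slowing long training runs.
  token <- .ad_state$bw_token <- .ad_state$bw_token + 1L
  nodes <- list()
  for (k in seq_along(outputs)) {
    node <- outputs[[k]]
    .ad_accum(node, grads[[k]])
    if (!identical(node$visit_token, token)) {
      node$visit_token <- token
      nodes[[length(nodes) + 1]] <- node
    }
  }
  # collect reachable subgraph
  i <- 1
  while (i <= length(nodes)) {
    for (p in nodes[[i]]$parents) {
      if (!p$requires) next
      if (!identical(p$visit_token, token)) {
        p$visit_token <- token
        nodes[[length(nodes) + 1]] <- p
      }
    }
    i <- i + 1
  }
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  for (n in nodes[ord]) {
    if (is.null(n$backward) || is.null(n$grad)) next
    n$backward(n$grad)
  }
  invisible(NULL)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise ops -------------------------------------------------------

ad_add <- function(a, b) {
  out <- ad_new_node(a$value + b$value, list(a, b))
  out$backward <- function(g) {
    .ad_accum(a, g)
    .ad_accum(b, g)
  }
  out
}

ad_mul <- function(a, b) {
  out <- ad_new_node(a$value * b$value, list(a, b))
  out$backward <- function(g) {
    .ad_accum(a, g * b$value)
    .ad_accum(b, g * a$value)
  }
  out
}

ad_scalar_mul <- function(x, s) {
  # s: plain numeric scalar or a length-1 ad_node
  if (inherits(s, "ad_node")) {
    out <- ad_new_node(x$value * as.numeric(s$value), list(x, s))
    out$backward <- function(g) {
      .ad_accum(x, g * as.numeric(s$value))
      .ad_accum(s, sum(g * x$value))
    }
  } else {
    out <- ad_new_node(x$value * s, list(x))
    out$backward <- function(g) .ad_accum(x, g * s)
  }
  out
}

ad_relu <- function(x) {
  mask <- x$value > 0
  out <- ad_new_node(x$value * mask, list(x))
  out$backward <- function(g) .ad_accum(x, g * mask)
  out
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  out <- ad_new_node(s, list(x))
  out$backward <- function(g) .ad_accum(x, g * s * (1 - s))
  out
}

ad_swish <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  out <- ad_new_node(x$value * s, list(x))
  out$backward <- function(g) .ad_accum(x, g * (s + x$value * s * (1 - s)))
  out
}

ad_exp <- function(x) {
  v <- exp(x$value)
  out <- ad_new_node(v, list(x))
  out$backward <- function(g) .ad_accum(x, g * v)
  out
}

ad_sqrt <- function(x, eps = 1e-12) {
  v <- sqrt(pmax(x$value, 0))
  out <- ad_new_node(v, list(x))
  out$backward <- function(g) .ad_accum(x, g / (2 * pmax(v, eps)))
  out
}

ad_clamp <- function(x, lo, hi) {
  mask <- x$value > lo & x$value < hi
  out <- ad_new_node(pmin(pmax(x$value, lo), hi), list(x))
  out$backward <- function(g) .ad_accum(x, g * mask)
  out
}

ad_vec_slice <- function(x, k) {
  out <- ad_new_node(as.numeric(x$value)[k], list(x))
  out$backward <- function(g) {
    gx <- numeric(length(x$value))
    gx[k] <- as.numeric(g)
    .ad_accum(x, gx)
  }
  out
}

# ---- shape ops -------------------------------------------------------------

ad_concat_c <- function(xs) {
  # concatenate (H, W, C_i) arrays along channels
  dims <- lapply(xs, function(x) dim(x$value))
  H <- dims[[1]][1]; W <- dims[[1]][2]
  Cs <- vapply(dims, function(d) d[3], numeric(1))
  value <- array(0, c(H, W, sum(Cs)))
  off <- 0
  for (k in seq_along(xs)) {
    value[, , off + seq_len(Cs[k])] <- xs[[k]]$value
    off <- off + Cs[k]
  }
  out <- ad_new_node(value, xs)
  out$backward <- function(g) {
    off <- 0
    for (k in seq_along(xs)) {
      .ad_accum(xs[[k]], g[, , off + seq_len(Cs[k]), drop = FALSE])
      off <- off + Cs[k]
    }
  }
  out
}

ad_gap <- function(x) {
  # global average pool (H, W, C) -> length-C vector
  d <- dim(x$value)
  m <- d[1] * d[2]
  v <- colMeans(matrix(x$value, m, d[3]))
  out <- ad_new_node(v, list(x))
  out$backward <- function(g) {
    gx <- rep(as.numeric(g) / m, each = m)
    dim(gx) <- d
    .ad_accum(x, gx)
  }
  out
}

ad_scale_channels <- function(x, gate) {
  # gate: length-C node; multiply each channel of (H, W, C)
  d <- dim(x$value)
  m <- d[1] * d[2]
  gx <- rep(as.numeric(gate$value), each = m)
  out_v <- x$value * gx
  dim(out_v) <- d
  out <- ad_new_node(out_v, list(x, gate))
  out$backward <- function(g) {
    .ad_accum(x, g * array(gx, d))
    .ad_accum(gate, colSums(matrix(g * x$value, m, d[3])))
  }
  out
}

ad_rep_gate <- function(g, each) {
  # expand a length-N gate vector to N*each channels (blockwise repeat)
  n <- length(g$value)
  out <- ad_new_node(rep(as.numeric(g$value), each = each), list(g))
  out$backward <- function(gr)
    .ad_accum(g, colSums(matrix(as.numeric(gr), each, n)))
  out
}

ad_broadcast_mul <- function(x, m) {
  # x: (H, W, C); m: (H, W, 1) spatial map applied to every channel
  d <- dim(x$value)
  mv <- array(rep(m$value[, , 1], d[3]), d)
  out <- ad_new_node(x$value * mv, list(x, m))
  out$backward <- function(g) {
    .ad_accum(x, g * mv)
    gm <- apply(g * x$value, c(1, 2), sum)
    .ad_accum(m, array(gm, c(d[1], d[2], 1)))
  }
  out
}

ad_upsample_nearest <- function(x, out_h, out_w) {
  # 2x nearest-neighbour upsampling, then deterministic crop/pad (edge
  # replication) to the requested size to absorb odd-size mismatches
  d <- dim(x$value)
  ri <- pmin(((seq_len(out_h) - 1) %/% 2) + 1, d[1])
  rj <- pmin(((seq_len(out_w) - 1) %/% 2) + 1, d[2])
  out_v <- x$value[ri, rj, , drop = FALSE]
  out <- ad_new_node(out_v, list(x))
  out$backward <- function(g) {
    gx <- array(0, d)
    for (c in seq_len(d[3])) {
      gc <- g[, , c]
      # scatter-add via tapply-free accumulation
      acc <- rowsum(t(rowsum(gc, ri)), rj)
      gx[sort(unique(ri)), sort(unique(rj)), c] <- t(acc)
    }
    .ad_accum(x, gx)
  }
  out
}

# ---- dense layers ----------------------------------------------------------

.conv_same_pad <- function(H, W, kh, kw, stride) {
  Ho <- ceiling(H / stride); Wo <- ceiling(W / stride)
  ph <- max((Ho - 1) * stride + kh - H, 0)
  pw <- max((Wo - 1) * stride + kw - W, 0)
  list(Ho = Ho, Wo = Wo, pad_top = ph %/% 2, pad_left = pw %/% 2)
}

ad_conv2d <- function(x, w, b = NULL, stride = 1L) {
  # x: (H, W, Cin); w: param (kh, kw, Cin, Cout); b: param length Cout or NULL
  d <- dim(x$value); wd <- dim(w$value)
  kh <- wd[1]; kw <- wd[2]; Cin <- wd[3]; Cout <- wd[4]
  p <- .conv_same_pad(d[1], d[2], kh, kw, stride)
  cols <- cpp_im2col(x$value, d[1], d[2], d[3], kh, kw, as.integer(stride),
                     p$pad_top, p$pad_left, p$Ho, p$Wo)
  wmat <- w$value
  dim(wmat) <- c(kh * kw * Cin, Cout)
  y <- cols %*% wmat
  if (!is.null(b)) y <- y + rep(as.numeric(b$value), each = p$Ho * p$Wo)
  dim(y) <- c(p$Ho, p$Wo, Cout)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  out <- ad_new_node(y, parents)
  out$backward <- function(g) {
    gm <- g
    dim(gm) <- c(p$Ho * p$Wo, Cout)
    if (w$requires) {
      gw <- crossprod(cols, gm)
      dim(gw) <- wd
      .ad_accum(w, gw)
    }
    if (!is.null(b) && b$requires) .ad_accum(b, colSums(gm))
    if (x$requires) {
      gcols <- tcrossprod(gm, wmat)
      gx <- cpp_col2im(gcols, d[1], d[2], d[3], kh, kw, as.integer(stride),
                       p$pad_top, p$pad_left, p$Ho, p$Wo)
      .ad_accum(x, gx)
    }
  }
  out
}

ad_dwconv2d <- function(x, w, stride = 1L) {
  # depthwise: w (kh, kw, C)
  d <- dim(x$value); wd <- dim(w$value)
  p <- .conv_same_pad(d[1], d[2], wd[1], wd[2], stride)
  out_v <- cpp_dwconv_fwd(x$value, w$value, d[1], d[2], d[3], wd[1], wd[2],
                          as.integer(stride), p$pad_top, p$pad_left,
                          p$Ho, p$Wo)
  out <- ad_new_node(out_v, list(x, w))
  out$backward <- function(g) {
    r <- cpp_dwconv_bwd(x$value, w$value, g, d[1], d[2], d[3], wd[1], wd[2],
                        as.integer(stride), p$pad_top, p$pad_left, p$Ho, p$Wo)
    .ad_accum(x, r$gx)
    .ad_accum(w, r$gw)
  }
  out
}

ad_fc <- function(x, w, b = NULL) {
  # x: length-n vector node; w: (n, m) param
  y <- as.numeric(crossprod(w$value, as.numeric(x$value)))
  if (!is.null(b)) y <- y + as.numeric(b$value)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  out <- ad_new_node(y, parents)
  out$backward <- function(g) {
    g <- as.numeric(g)
    if (w$requires) .ad_accum(w, outer(as.numeric(x$value), g))
    if (!is.null(b) && b$requires) .ad_accum(b, g)
    if (x$requires) .ad_accum(x, as.numeric(w$value %*% g))
  }
  out
}

# ---- normalization ---------------------------------------------------------

ad_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[3]
  if (C %% groups != 0)
    stop("channel count ", C, " not divisible by ", groups, " groups")
  cg <- C / groups
  hw <- d[1] * d[2]
  m <- hw * cg
  grp <- rep(seq_len(groups), each = cg)
  xm <- matrix(x$value, hw, C)
  ch_sum <- colSums(xm)
  ch_sq <- colSums(xm * xm)
  g_sum <- rowsum(ch_sum, grp)[, 1]
  g_sq <- rowsum(ch_sq, grp)[, 1]
  mu <- g_sum / m
  sd_inv <- 1 / sqrt(g_sq / m - mu^2 + eps)
  mu_c <- rep(mu[grp], each = hw)
  si_c <- rep(sd_inv[grp], each = hw)
  xhat <- (as.numeric(xm) - mu_c) * si_c
  gam <- rep(as.numeric(gamma$value), each = hw)
  out_v <- gam * xhat
  if (!is.null(beta))
    out_v <- out_v + rep(as.numeric(beta$value), each = hw)
  dim(out_v) <- d
  parents <- if (is.null(beta)) list(x, gamma) else list(x, gamma, beta)
  out <- ad_new_node(out_v, parents)
  out$backward <- function(gr) {
    grm <- matrix(gr, hw, C)
    if (!is.null(beta) && beta$requires)
      .ad_accum(beta, colSums(grm))
    xhat_m <- matrix(xhat, hw, C)
    if (gamma$requires)
      .ad_accum(gamma, colSums(grm * xhat_m))
    if (x$requires) {
      dxhat <- as.numeric(grm) * gam
      dxh_m <- matrix(dxhat, hw, C)
      s1 <- rowsum(colSums(dxh_m), grp)[, 1]
      s2 <- rowsum(colSums(dxh_m * xhat_m), grp)[, 1]
      gx <- si_c * (dxhat - rep(s1[grp], each = hw) / m -
                      xhat * rep(s2[grp], each = hw) / m)
      dim(gx) <- d
      .ad_accum(x, gx)
    }
  }
  out
}

# Batch normalization at batch size 1. With a single image per step the
# batch statistics degenerate to per-image spatial statistics, so those are
# used in BOTH training and evaluation (instance-style normalization):
# using running averages at eval while training normalizes per image would
# create a train/eval distribution mismatch. Running estimates are still
# tracked for diagnostics.
ad_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.1,
                         eps = 1e-5) {
  d <- dim(x$value)
  m <- d[1] * d[2]
  xm <- matrix(x$value, m, d[3])
  mu <- colMeans(xm)
  va <- colMeans(xm * xm) - mu^2
  if (training) {
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  }
  sd_inv <- 1 / sqrt(va + eps)
  mu_c <- rep(mu, each = m)
  si_c <- rep(sd_inv, each = m)
  xhat <- (as.numeric(xm) - mu_c) * si_c
  gam <- rep(as.numeric(gamma$value), each = m)
  out_v <- gam * xhat + rep(as.numeric(beta$value), each = m)
  dim(out_v) <- d
  out <- ad_new_node(out_v, list(x, gamma, beta))
  out$backward <- function(gr) {
    grm <- matrix(gr, m, d[3])
    xhat_m <- matrix(xhat, m, d[3])
    .ad_accum(beta, colSums(grm))
    .ad_accum(gamma, colSums(grm * xhat_m))
    if (x$requires) {
      dxhat <- as.numeric(grm) * gam
      dxh_m <- matrix(dxhat, m, d[3])
      s1 <- colSums(dxh_m)
      s2 <- colSums(dxh_m * xhat_m)
      gx <- si_c * (dxhat - rep(s1, each = m) / m -
                      xhat * rep(s2, each = m) / m)
      dim(gx) <- d
      .ad_accum(x, gx)
    }
  }
  out
}

# ---- alignment sampling ----------------------------------------------------

ad_offset_sample <- function(B, O) {
  d <- dim(B$value)
  out_v <- cpp_offset_sample_fwd(B$value, O$value, d[1], d[2])
  out <- ad_new_node(out_v, list(B, O))
  out$backward <- function(g) {
    r <- cpp_offset_sample_bwd(B$value, O$value, g, d[1], d[2])
    .ad_accum(B, r$gB)
    .ad_accum(O, r$gO)
  }
  out
}
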