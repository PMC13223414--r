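# Engine-level checks: every layer operation's backward is validated
# against central finite differences of its forward value.

ad <- function(name) get(name, envir = asNamespace("koadetect"))

numeric_grad <- function(f, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

check_op <- function(build, x0, tol = 1e-5) {
  p <- ad("ad_param")(x0)
  out <- build(p)
  w <- array(runif(length(out$value)), dim(out$value) %||% length(out$value))
  ad("ad_zero_grad")(list(p))
  ad("ad_backward")(list(out), list(w))
  f <- function(x) {
    q <- ad("ad_param")(x)
    sum(build(q)$value * w)
  }
  expect_equal(as.numeric(p$grad), as.numeric(numeric_grad(f, x0)),
               tolerance = tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("elementwise and pooling ops backpropagate exactly", {
  set.seed(1)
  x <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  check_op(function(p) ad("ad_sigmoid")(p), x)
  check_op(function(p) ad("ad_swish")(p), x)
  check_op(function(p) ad("ad_exp")(p), x * 0.3)
  check_op(function(p) ad("ad_gap")(p), x)
  check_op(function(p) ad("ad_clamp")(p, -0.5, 0.5), x)
})

test_that("convolutions backpropagate to inputs and weights", {
  set.seed(2)
  x <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
  w <- array(rnorm(3 * 3 * 3 * 4, sd = 0.5), c(3, 3, 3, 4))
  b <- rnorm(4)
  # input gradient
  check_op(function(p) ad("ad_conv2d")(p, ad("ad_param")(w),
                                       ad("ad_param")(b)), x)
  # weight gradient (stride 2)
  px <- ad("ad_const")(x)
  check_w <- function(w0) {
    pw <- ad("ad_param")(w0)
    out <- ad("ad_conv2d")(px, pw, stride = 2)
    g <- array(runif(length(out$value)), dim(out$value))
    ad("ad_backward")(list(out), list(g))
    f <- function(wv) sum(ad("ad_conv2d")(px, ad("ad_param")(wv),
                                          stride = 2)$value * g)
    expect_equal(as.numeric(pw$grad), as.numeric(numeric_grad(f, w0)),
                 tolerance = 1e-5)
  }
  check_w(w)
  # depthwise
  dw <- array(rnorm(3 * 3 * 3, sd = 0.5), c(3, 3, 3))
  check_op(function(p) ad("ad_dwconv2d")(p, ad("ad_param")(dw), stride = 2), x)
})

test_that("normalization layers backpropagate exactly", {
  set.seed(3)
  x <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  gm <- runif(6, 0.5, 1.5); bt <- rnorm(6)
  check_op(function(p)
    ad("ad_groupnorm")(p, ad("ad_param")(gm), ad("ad_param")(bt), 3), x,
    tol = 1e-4)
  st <- new.env(); st$mean <- numeric(6); st$var <- rep(1, 6)
  check_op(function(p)
    ad("ad_batchnorm")(p, ad("ad_param")(gm), ad("ad_param")(bt), st,
                       training = FALSE), x, tol = 1e-4)
  expect_error(ad("ad_groupnorm")(ad("ad_param")(x), ad("ad_param")(gm),
                                  ad("ad_param")(bt), 5),
               "not divisible")
})

test_that("nested op calls keep a valid topological order", {
  # regression guard: outer nodes must be created after their parents even
  # when the whole chain is written as one nested expression
  p <- ad("ad_param")(array(0.1, c(2, 2, 1)))
  sc <- ad("ad_param")(1)
  d <- ad("ad_scalar_mul")(
    ad("ad_exp")(ad("ad_clamp")(ad("ad_scalar_mul")(p, sc), -8, 8)), 8)
  ad("ad_backward")(list(d), list(array(1, c(2, 2, 1))))
  expect_equal(p$grad[1], 8 * exp(0.1), tolerance = 1e-12)
  expect_equal(sc$grad, sum(8 * 0.1 * exp(0.1) * rep(1, 4)),
               tolerance = 1e-12)
})

test_that("offset sampling equals direct indexing at integer offsets", {
  set.seed(4)
  B <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  O <- array(sample(-2:2, 5 * 5 * 8, TRUE), c(5, 5, 8))
  out <- ad("ad_offset_sample")(ad("ad_const")(B), ad("ad_const")(O))$value
  for (c4 in 1:4) for (i in 1:5) for (j in 1:5) {
    si <- min(max(i + O[i, j, 2 * c4 - 1], 1), 5)
    sj <- min(max(j + O[i, j, 2 * c4], 1), 5)
    expect_equal(out[i, j, c4], B[si, sj, c4])
  }
})

test_that("fractional offsets bilinearly interpolate (two-cell ramp)", {
  B <- array(0, c(2, 2, 4))
  B[1, 1, 1] <- 2; B[2, 1, 1] <- 6  # vertical ramp in boundary channel 1
  O <- array(0, c(2, 2, 8))
  O[1, 1, 1] <- 0.5                 # half-cell step down the ramp
  out <- ad("ad_offset_sample")(ad("ad_const")(B), ad("ad_const")(O))$value
  expect_equal(out[1, 1, 1], mean(c(2, 6)))
})

test_that("offset sampling backward matches finite differences off the
           integer knots", {
  set.seed(6)
  B0 <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  O0 <- array(runif(4 * 4 * 8, -0.8, 0.8) + 0.13, c(4, 4, 8))
  g <- array(runif(4 * 4 * 4), c(4, 4, 4))
  pB <- ad("ad_param")(B0); pO <- ad("ad_param")(O0)
  out <- ad("ad_offset_sample")(pB, pO)
  ad("ad_backward")(list(out), list(g))
  fB <- function(Bv) sum(ad("ad_offset_sample")(ad("ad_param")(Bv),
                                                ad("ad_const")(O0))$value * g)
  fO <- function(Ov) sum(ad("ad_offset_sample")(ad("ad_const")(B0),
                                                ad("ad_param")(Ov))$value * g)
  expect_equal(as.numeric(pB$grad), as.numeric(numeric_grad(fB, B0)),
               tolerance = 1e-5)
  expect_equal(as.numeric(pO$grad), as.numeric(numeric_grad(fO, O0)),
               tolerance = 1e-4)
})

test_that("upsampling and fusion plumbing backpropagate", {
  set.seed(7)
  x <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  check_op(function(p) ad("ad_upsample_nearest")(p, 4, 4), x)
  check_op(function(p) ad("ad_upsample_nearest")(p, 3, 4), x)  # odd crop
  g6 <- rnorm(6)
  check_op(function(p) ad("ad_rep_gate")(p, 4), g6)
  gate3 <- runif(3)
  check_op(function(p) ad("ad_scale_channels")(
    p, ad("ad_param")(gate3)), x)
  map1 <- array(runif(4), c(2, 2, 1))
  check_op(function(p) ad("ad_broadcast_mul")(
    p, ad("ad_param")(map1)), x)
})
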