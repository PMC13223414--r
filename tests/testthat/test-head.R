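test_that("the interactive extractor has six retained nonnegative layers
           preserving spatial size", {
  out <- tiny_forward()
  lv <- out$levels[[1]]
  expect_equal(length(lv$inter), 6)
  for (m in lv$inter) {
    expect_equal(dim(m$value)[1:2], dim(out$pyramid$P3$value)[1:2])
    expect_true(all(m$value >= 0))
  }
})

test_that("group-normalization configuration is 32 groups and rejects
           indivisible widths", {
  cfg <- tiny_detector_config()
  expect_equal(cfg$gn_groups, 32)
  expect_equal(detector_config()$gn_groups, 32)
  expect_error(build_head(koadetect:::param_registry(), channels = 24),
               "divisible")
})

test_that("layer attention produces per-task weights in (0,1), 0.5 at zero
           weights", {
  out <- tiny_forward()
  for (lv in out$levels) {
    expect_true(all(lv$omega_cls$value > 0 & lv$omega_cls$value < 1))
    expect_true(all(lv$omega_loc$value > 0 & lv$omega_loc$value < 1))
    expect_equal(length(lv$omega_cls$value), 6)
  }
  reg <- koadetect:::param_registry()
  hd <- withr::with_seed(1, build_head(reg, channels = 32))
  for (nm in grep("^head.att", names(reg$params), value = TRUE))
    reg$params[[nm]]$value[] <- 0
  x <- koadetect:::ad_const(array(abs(rnorm(8 * 8 * 32)), c(8, 8, 32)))
  lo <- hd$forward(x, 1)
  expect_equal(unname(lo$omega_cls$value), rep(0.5, 6), tolerance = 1e-12)
})

test_that("task predictions respect their ranges and shapes", {
  out <- tiny_forward()
  for (lv in out$levels) {
    expect_true(all(lv$P$value > 0 & lv$P$value < 1))
    expect_equal(dim(lv$P$value)[3], 5)        # five KL grades
    expect_true(all(lv$dist$value >= 0))       # distances nonnegative
    expect_equal(dim(lv$dist$value)[3], 4)
    expect_equal(dim(lv$M$value)[3], 1)
    expect_true(all(lv$M$value > 0 & lv$M$value < 1))
    expect_equal(dim(lv$O$value)[3], 8)        # 2 offsets x 4 boundaries
  }
})

test_that("classification alignment is the geometric mean with its
           betweenness property", {
  out <- tiny_forward()
  for (lv in out$levels) {
    p <- lv$P$value
    m <- array(rep(lv$M$value[, , 1], dim(p)[3]), dim(p))
    expect_equal(lv$P_align$value, sqrt(p * m), tolerance = 1e-12)
    expect_true(all(lv$P_align$value >= pmin(p, m) - 1e-12))
    expect_true(all(lv$P_align$value <= pmax(p, m) + 1e-12))
  }
  # M == P would leave P unchanged: sqrt(P * P) = P
  pv <- matrix(runif(16, 0.1, 0.9), 4)
  expect_equal(sqrt(pv * pv), pv)
})

test_that("zero offsets leave localization unchanged; each boundary is
           moved independently", {
  reg <- koadetect:::param_registry()
  hd <- withr::with_seed(2, build_head(reg, channels = 32))
  x <- koadetect:::ad_const(array(abs(rnorm(8 * 8 * 32)), c(8, 8, 32)))
  lo <- hd$forward(x, 1)
  # O weights are zero-initialized, so alignment starts as the identity
  expect_true(all(lo$O$value == 0))
  expect_equal(lo$dist_align$value, lo$dist$value, tolerance = 1e-12)
  # shift only boundary 3 (channels 5,6): other boundaries unchanged
  reg$params[["head.O.2.b"]]$value[5] <- 1
  lo2 <- hd$forward(x, 1)
  expect_equal(lo2$dist_align$value[, , c(1, 2, 4)],
               lo$dist_align$value[, , c(1, 2, 4)], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(lo2$dist_align$value[, , 3],
                                lo$dist_align$value[, , 3])))
})

test_that("disabling alignment reduces the head to a plain decoupled
           head", {
  reg <- koadetect:::param_registry()
  hd <- withr::with_seed(3, build_head(reg, channels = 32,
                                       alignment = FALSE))
  x <- koadetect:::ad_const(array(abs(rnorm(8 * 8 * 32)), c(8, 8, 32)))
  lo <- hd$forward(x, 1)
  expect_null(lo$M)
  expect_null(lo$O)
  expect_identical(lo$P_align$value, lo$P$value)
  expect_identical(lo$dist_align$value, lo$dist$value)
})

test_that("the head is deterministic in evaluation mode", {
  m <- tiny_model()
  img <- tiny_forward_image()
  a <- m$forward(img, training = FALSE)
  b <- m$forward(img, training = FALSE)
  for (l in seq_along(a$levels)) {
    expect_identical(a$levels[[l]]$P_align$value,
                     b$levels[[l]]$P_align$value)
    expect_identical(a$levels[[l]]$dist_align$value,
                     b$levels[[l]]$dist_align$value)
  }
})

test_that("decoded level boxes are valid and anchored on the half-cell
           grid", {
  out <- tiny_forward()
  dec <- decode_level(out$levels[[2]])
  expect_equal(nrow(dec$boxes), 16)  # 4x4 level
  expect_true(all(dec$boxes[, 3] >= dec$boxes[, 1]))
  expect_true(all(dec$boxes[, 4] >= dec$boxes[, 2]))
  expect_true(all(dec$scores > 0 & dec$scores < 1))
  expect_equal(dec$anchors$stride[1], 16)
})
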