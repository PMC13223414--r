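test_that("EIoU components reproduce hand-evaluated values", {
  z <- eiou_loss(c(0, 0, 4, 4), c(0, 0, 4, 4))
  expect_equal(z$total, 0)
  expect_equal(z$iou_term + z$distance_term + z$aspect_term, z$total)

  # disjoint corner case evaluated term by term by hand:
  # IoU 0; enclosing (0,0,4,4) so c^2 = 32; centers (1,1) and (3,3) so
  # rho^2 = 8; equal widths and heights so no edge-length penalty
  r <- eiou_loss(c(0, 0, 2, 2), c(2, 2, 4, 4))
  expect_equal(r$iou_term, 1)
  expect_equal(r$distance_term, 8 / 32)
  expect_equal(r$aspect_term, 0)
  expect_equal(r$total, 1.25)

  set.seed(9)
  for (k in 1:200) {
    a <- random_box(); b <- random_box()
    r <- eiou_loss(a, b)
    expect_gte(r$total, (1 - box_iou(a, b)) - 1e-12)
    same_center <- isTRUE(all.equal((a[1] + a[3]) / 2, (b[1] + b[3]) / 2)) &&
      isTRUE(all.equal((a[2] + a[4]) / 2, (b[2] + b[4]) / 2))
    same_edges <- isTRUE(all.equal(a[3] - a[1], b[3] - b[1])) &&
      isTRUE(all.equal(a[4] - a[2], b[4] - b[2]))
    if (!(same_center && same_edges))
      expect_gt(r$total, 1 - box_iou(a, b))
  }
})

test_that("EIoU is translation invariant and scale covariant", {
  set.seed(15)
  for (k in 1:30) {
    a <- random_box(); b <- random_box()
    sh <- runif(2, -50, 50)
    r0 <- eiou_loss(a, b)
    r1 <- eiou_loss(a + sh[c(1, 2, 1, 2)], b + sh[c(1, 2, 1, 2)])
    expect_equal(r1$total, r0$total, tolerance = 1e-9)
    s <- runif(1, 0.1, 10)
    r2 <- eiou_loss(a * s, b * s)
    expect_equal(r2$iou_term, r0$iou_term, tolerance = 1e-9)
    expect_equal(r2$distance_term, r0$distance_term, tolerance = 1e-9)
    expect_equal(r2$aspect_term, r0$aspect_term, tolerance = 1e-9)
  }
})

test_that("CIoU reduces to DIoU at equal aspect ratio and flags the
           opposite-sign width/height gradients", {
  expect_equal(ciou_loss(c(0, 0, 4, 4), c(0, 0, 4, 4)), 0)
  expect_error(ciou_loss(c(0, 0, 0, 4), c(0, 0, 2, 2)), "positive-area")
  g <- ciou_aspect_gradients(c(0, 0, 4, 2), c(0, 0, 2, 2))
  expect_true(g["dv_dw"] * g["dv_dh"] < 0)
  set.seed(4)
  for (k in 1:100) {
    b <- random_box(min_size = 1)
    s <- runif(1, 0.3, 3); sh <- runif(2, -5, 5)
    a <- c(b[1] * s + sh[1], b[2] * s + sh[2],
           b[1] * s + sh[1] + (b[3] - b[1]) * s,
           b[2] * s + sh[2] + (b[4] - b[2]) * s)  # same aspect ratio
    expect_equal(ciou_loss(a, b), diou_loss(a, b), tolerance = 1e-9)
  }
})

test_that("focal loss reduces to BCE at gamma 0 and matches hand arithmetic", {
  set.seed(2)
  p <- runif(40, 0.05, 0.95)
  t <- rbinom(40, 1, 0.3)
  plain <- cls_loss_config(gamma = 0, alpha = 0)
  bce <- sum(-(t * log(p) + (1 - t) * log(1 - p))) / max(sum(t), 1)
  expect_equal(focal_classification_loss(p, t, plain), bce,
               tolerance = 1e-12)
  # single positive, p = 0.5, gamma = 2, unit scale
  expect_equal(
    focal_classification_loss(0.5, 1, cls_loss_config(gamma = 2, alpha = 0)),
    0.25 * log(2), tolerance = 1e-12)
  expect_equal(0.25 * log(2), 0.1733, tolerance = 1e-4)
})

test_that("well-classified negatives are suppressed and p_t monotonicity
           holds", {
  cfg <- cls_loss_config()
  base <- focal_classification_loss(c(0.8, rep(1e-7, 100)),
                                    c(1, rep(0, 100)), cfg)
  doubled <- focal_classification_loss(c(0.8, rep(1e-7, 200)),
                                       c(1, rep(0, 200)), cfg)
  expect_lt(abs(doubled - base), 1e-6)
  ps <- seq(0.02, 0.98, by = 0.02)
  vals_pos <- vapply(ps, function(p)
    focal_classification_loss(p, 1, cfg), numeric(1))
  expect_false(is.unsorted(rev(vals_pos)))  # decreasing in p_t = p
  vals_neg <- vapply(ps, function(p)
    focal_classification_loss(p, 0, cfg), numeric(1))
  expect_false(is.unsorted(vals_neg))       # increasing in p (p_t = 1 - p)
})

test_that("weighted BCE matches hand arithmetic and is permutation
           invariant", {
  expect_lt(weighted_bce(c(1 - 1e-7, 1e-7), c(1, 0)), 1e-6)
  expect_equal(weighted_bce(0.5, 1), log(2), tolerance = 1e-12)
  set.seed(8)
  p <- runif(30); y <- rbinom(30, 1, 0.5)
  perm <- sample(30)
  expect_equal(weighted_bce(p, y), weighted_bce(p[perm], y[perm]))
  expect_error(weighted_bce(c(0.5, 0.5), 1), "lengths differ")
})

test_that("the composite loss decomposes into its parts", {
  set.seed(13)
  n <- 50
  scores <- matrix(runif(n * 5, 0.01, 0.99), n, 5)
  target <- matrix(0, n, 5)
  pos <- sample(n, 6)
  target[cbind(pos, sample(5, 6, TRUE))] <- 1
  pb <- t(vapply(seq_along(pos), function(i) random_box(), numeric(4)))
  gb <- t(vapply(seq_along(pos), function(i) random_box(), numeric(4)))
  colnames(pb) <- colnames(gb) <- c("x_min", "y_min", "x_max", "y_max")
  lv <- total_detection_loss(scores, target, pb, gb)
  cls <- focal_classification_loss(as.numeric(scores), as.numeric(target))
  reg <- mean(vapply(seq_along(pos), function(k)
    eiou_loss(pb[k, ], gb[k, ])$total, numeric(1)))
  expect_equal(lv$cls_loss, cls)
  expect_equal(lv$reg_loss, reg)
  expect_equal(lv$total, cls + reg)
  # no positives: total equals the classification term exactly
  lv0 <- total_detection_loss(scores, matrix(0, n, 5))
  expect_equal(lv0$reg_loss, 0)
  expect_equal(lv0$total, lv0$cls_loss)
  # near-perfect predictions give near-zero loss
  perfect_scores <- matrix(1e-7, n, 5)
  perfect_scores[target == 1] <- 1 - 1e-7
  lvp <- total_detection_loss(perfect_scores, target, gb, gb)
  expect_lt(lvp$total, 1e-3)
})
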