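# Shared fixtures. Heavy objects (a built tiny detector and one forward
# pass) are created lazily and cached so structural tests across files pay
# for them once.

.fixture_env <- new.env(parent = emptyenv())

tiny_model <- function() {
  if (is.null(.fixture_env$model))
    .fixture_env$model <- build_detector(tiny_detector_config(), seed = 42)
  .fixture_env$model
}

tiny_forward <- function() {
  if (is.null(.fixture_env$forward)) {
    s <- generate_phantom("K2", tiny_phantom_config(), seed = 7)
    .fixture_env$forward <- tiny_model()$forward(s$image, training = FALSE)
    .fixture_env$forward_image <- s$image
  }
  .fixture_env$forward
}

tiny_forward_image <- function() {
  tiny_forward()
  .fixture_env$forward_image
}

random_box <- function(lo = 0, hi = 20, min_size = 0.5) {
  x <- sort(runif(2, lo, hi))
  y <- sort(runif(2, lo, hi))
  c(x[1], y[1], max(x[2], x[1] + min_size), max(y[2], y[1] + min_size))
}

# independent IoU oracle: rasterize both boxes on a fine sub-grid of cell
# centers and count cells. Axis-aligned boxes factorize, so the 2-D counts
# are products of 1-D counts and the grid can be very fine.
rasterized_iou <- function(a, b, cells_per_unit = 400) {
  lo_x <- floor(min(a[1], b[1])); hi_x <- ceiling(max(a[3], b[3]))
  lo_y <- floor(min(a[2], b[2])); hi_y <- ceiling(max(a[4], b[4]))
  n_x <- max(1, (hi_x - lo_x)) * cells_per_unit
  n_y <- max(1, (hi_y - lo_y)) * cells_per_unit
  cx <- lo_x + (seq_len(n_x) - 0.5) * (hi_x - lo_x) / n_x
  cy <- lo_y + (seq_len(n_y) - 0.5) * (hi_y - lo_y) / n_y
  count <- function(box) {
    sum(cx >= box[1] & cx <= box[3]) * sum(cy >= box[2] & cy <= box[4])
  }
  na <- count(a); nb <- count(b)
  ov <- c(max(a[1], b[1]), max(a[2], b[2]), min(a[3], b[3]), min(a[4], b[4]))
  ni <- if (ov[3] > ov[1] && ov[4] > ov[2]) count(ov) else 0
  un <- na + nb - ni
  if (un == 0) return(0)
  ni / un
}
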