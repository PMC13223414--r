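make_sample <- function(seed, w = 40, h = 30, n_box = 2) {
  withr::with_seed(seed, {
    img <- matrix(sample(0:255, w * h, TRUE), h, w)
    ann <- do.call(rbind, lapply(seq_len(n_box), function(i) {
      x1 <- sample(0:(w - 10), 1); y1 <- sample(0:(h - 10), 1)
      data.frame(x_min = x1, y_min = y1,
                 x_max = x1 + sample(4:9, 1), y_max = y1 + sample(4:9, 1),
                 label = sample(paste0("K", 0:4), 1))
    }))
    koa_sample(img, paste0("sample", seed), ann)
  })
}

test_that("VOC XML writing and reading round-trip integer boxes", {
  for (seed in 1:10) {
    s <- make_sample(seed)
    path <- tempfile(fileext = ".xml")
    write_voc_xml(s, path)
    back <- read_voc_xml(path)
    expect_equal(back$filename, paste0(s$id, ".png"))
    expect_equal(back$width, ncol(s$image))
    expect_equal(back$height, nrow(s$image))
    expect_equal(back$annotations, s$annotations, ignore_attr = TRUE)
    unlink(path)
  }
})

test_that("VOC reader handles empty objects and rejects bad input", {
  s <- koa_sample(matrix(0, 20, 20), "empty")
  path <- tempfile(fileext = ".xml")
  write_voc_xml(s, path)
  expect_equal(nrow(read_voc_xml(path)$annotations), 0)
  writeLines("<annotation><object>", path)
  expect_error(read_voc_xml(path), "malformed")
  unlink(path)
  expect_error(koa_sample(matrix(0, 10, 10), "bad",
                          data.frame(x_min = 0, y_min = 0, x_max = 5,
                                     y_max = 5, label = "K9")),
               "permitted labels")
  expect_error(koa_sample(matrix(0, 10, 10), "oob",
                          data.frame(x_min = 0, y_min = 0, x_max = 15,
                                     y_max = 5, label = "K1")),
               "outside image bounds")
})

test_that("annotation CSV aggregates rows per image and validates", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("filename,x_min,y_min,x_max,y_max,label",
               "a.png,1,2,11,12,KL0",
               "a.png,3,4,13,14,K2",
               "b.png,5,6,15,16,KL4"), path)
  sets <- read_annotations_csv(path)
  expect_equal(length(sets), 2)
  expect_equal(nrow(sets[["a.png"]]), 2)
  expect_equal(nrow(sets[["b.png"]]), 1)
  expect_equal(sets[["a.png"]]$label, c("K0", "K2"))  # aliases accepted
  writeLines(c("filename,x_min,y_min,x_max,y_max,label",
               "a.png,1,2,11,12,K0",
               "a.png,oops,4,13,14,K2"), path)
  expect_error(read_annotations_csv(path), "row 2")
  writeLines("filename,x_min,y_min,x_max,y_max,label", path)
  expect_equal(length(read_annotations_csv(path)), 0)
  unlink(path)
})

test_that("CSV and XML writers agree on coordinates", {
  samples <- lapply(21:23, make_sample)
  csv <- tempfile(fileext = ".csv")
  write_annotations_csv(samples, csv)
  sets <- read_annotations_csv(csv)
  for (s in samples) {
    xml <- tempfile(fileext = ".xml")
    write_voc_xml(s, xml)
    expect_equal(sets[[paste0(s$id, ".png")]][, 1:4],
                 read_voc_xml(xml)$annotations[, 1:4],
                 ignore_attr = TRUE)
    unlink(xml)
  }
  unlink(csv)
})

test_that("the stratified split reproduces the published per-grade
           composition", {
  totals <- c(514, 477, 232, 221, 206)
  labels <- rep(paste0("K", 0:4), times = totals)
  sp <- stratified_split(labels, 0.8, seed = 1)
  expect_equal(sp$counts$train, c(411, 381, 185, 176, 164))
  expect_equal(sp$counts$test, c(103, 96, 47, 45, 42))
  expect_equal(length(sp$train), 1317)
  expect_equal(length(sp$test), 333)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
})

test_that("split membership is seed-deterministic with seed-independent
           counts", {
  labels <- rep(paste0("K", 0:4), times = c(9, 7, 6, 5, 11))
  a <- stratified_split(labels, 0.8, seed = 4)
  b <- stratified_split(labels, 0.8, seed = 4)
  c <- stratified_split(labels, 0.8, seed = 99)
  expect_identical(a$train, b$train)
  expect_false(identical(a$train, c$train))
  expect_equal(a$counts, c$counts)
  expect_equal(a$counts$train, floor(0.8 * c(9, 7, 6, 5, 11)))
  # every nonempty class keeps a test sample when n * 0.2 >= 1
  expect_true(all(a$counts$test >= 1))
})

test_that("horizontal flip is an involution with the stated box
           arithmetic", {
  s <- make_sample(31, w = 100, h = 60)
  s$annotations <- data.frame(x_min = 10, y_min = 5, x_max = 30, y_max = 25,
                              label = "K1")
  f <- augment_sample(s, "hflip", seed = 1)
  expect_equal(as.numeric(f$annotations[1, 1:4]), c(70, 5, 90, 25))
  ff <- augment_sample(f, "hflip", seed = 1)
  expect_identical(ff$image, s$image)
  expect_equal(ff$annotations, s$annotations, ignore_attr = TRUE)
})

test_that("rotation and cropping keep boxes inside the frame", {
  s <- make_sample(32, w = 60, h = 60)
  r0 <- augment_sample(s, "rotate", seed = 2, rotate_range = 0)
  expect_identical(r0$image, s$image)
  expect_equal(r0$annotations, s$annotations, ignore_attr = TRUE)
  for (seed in 1:8) {
    a <- augment_sample(s, c("hflip", "rotate", "random_crop"), seed = seed)
    if (nrow(a$annotations)) {
      expect_true(all(a$annotations$x_min >= 0))
      expect_true(all(a$annotations$y_min >= 0))
      expect_true(all(a$annotations$x_max <= ncol(a$image)))
      expect_true(all(a$annotations$y_max <= nrow(a$image)))
      apply(a$annotations[, 1:4], 1, validate_box)
    }
    b <- augment_sample(s, c("hflip", "rotate", "random_crop"), seed = seed)
    expect_identical(a$image, b$image)  # seed determinism
  }
  expect_error(augment_sample(s, "zoom"), "unknown augmentation")
})

test_that("PNG round trip preserves 8-bit intensities", {
  img <- matrix(sample(0:255, 400, TRUE), 20, 20)
  path <- tempfile(fileext = ".png")
  write_image_png(img, path)
  expect_equal(read_image_png(path), img, ignore_attr = TRUE)
  unlink(path)
})
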