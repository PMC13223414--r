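# Dataset I/O: 8-bit grayscale PNG images, PASCAL VOC XML and CSV
# annotations, stratified 8:2 splitting, and runtime augmentation
# (horizontal flip, rotation, random crop).
#
# Internal coordinates are continuous with origin at the top-left pixel
# corner; VOC XML stores 1-based inclusive pixel indices, so mins are
# shifted by 1 on read/write and the formats round-trip losslessly on
# integer fixtures.

#' Construct an image sample
#'
#' @param image H x W matrix of integer intensities in `[0, 255]`.
#' @param id Image identifier (used as the file stem).
#' @param annotations Data frame `x_min,y_min,x_max,y_max,label`.
#' @return A `koa_sample` list.
#' @export
koa_sample <- function(image, id, annotations = NULL) {
  image <- as.matrix(image)
  if (any(image < 0 | image > 255))
    stop("pixel values must lie in [0, 255]")
  if (is.null(annotations))
    annotations <- data.frame(x_min = numeric(0), y_min = numeric(0),
                              x_max = numeric(0), y_max = numeric(0),
                              label = character(0))
  if (nrow(annotations)) {
    annotations$label <- normalize_grade(annotations$label)
    apply(annotations[, 1:4], 1, validate_box)
    w <- ncol(image); h <- nrow(image)
    if (any(annotations$x_min < 0 | annotations$y_min < 0 |
              annotations$x_max > w | annotations$y_max > h))
      stop("annotation box outside image bounds for sample ", id)
  }
  structure(list(image = image, id = id, annotations = annotations),
            class = "koa_sample")
}

#' Read / write an 8-bit grayscale PNG
#' @param path PNG file path.
#' @return Matrix of intensities in `[0, 255]`.
#' @export
read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  round(m * 255)
}

#' @rdname read_image_png
#' @param image Intensity matrix.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Write a sample's annotations as PASCAL VOC XML
#'
#' @param sample A [koa_sample()].
#' @param path Output file.
#' @export
write_voc_xml <- function(sample, path) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", paste0(sample$id, ".png"))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(ncol(sample$image)))
  xml2::xml_add_child(size, "height", as.character(nrow(sample$image)))
  xml2::xml_add_child(size, "depth", "1")
  ann <- sample$annotations
  if (nrow(ann)) {
    for (k in seq_len(nrow(ann))) {
      ob <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(ob, "name", sub("^K", "KL", ann$label[k]))
      bb <- xml2::xml_add_child(ob, "bndbox")
      xml2::xml_add_child(bb, "xmin", as.character(round(ann$x_min[k]) + 1))
      xml2::xml_add_child(bb, "ymin", as.character(round(ann$y_min[k]) + 1))
      xml2::xml_add_child(bb, "xmax", as.character(round(ann$x_max[k])))
      xml2::xml_add_child(bb, "ymax", as.character(round(ann$y_max[k])))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read PASCAL VOC XML annotations
#'
#' @param path XML file.
#' @return List with `filename`, `width`, `height` and the `annotations`
#'   data frame in internal continuous coordinates.
#' @export
read_voc_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed VOC XML at ", path,
                                           ": ", conditionMessage(e)))
  objs <- xml2::xml_find_all(doc, ".//object")
  num <- function(node, tag)
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, tag)))
  ann <- if (length(objs)) {
    data.frame(
      x_min = vapply(objs, num, numeric(1), ".//xmin") - 1,
      y_min = vapply(objs, num, numeric(1), ".//ymin") - 1,
      x_max = vapply(objs, num, numeric(1), ".//xmax"),
      y_max = vapply(objs, num, numeric(1), ".//ymax"),
      label = normalize_grade(vapply(objs, function(o)
        xml2::xml_text(xml2::xml_find_first(o, ".//name")), character(1))))
  } else {
    data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
               y_max = numeric(0), label = character(0))
  }
  list(filename = xml2::xml_text(xml2::xml_find_first(doc, ".//filename")),
       width = num(doc, ".//size/width"),
       height = num(doc, ".//size/height"),
       annotations = ann)
}

#' Read a flat annotation CSV
#'
#' Dialect: comma-separated with header
#' `filename,x_min,y_min,x_max,y_max,label`; multiple rows per image are
#' aggregated by filename.
#'
#' @param path CSV file.
#' @return Named list of annotation data frames, one per filename.
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("filename", "x_min", "y_min", "x_max", "y_max", "label")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have header ", paste(need, collapse = ","))
  for (col in c("x_min", "y_min", "x_max", "y_max")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric coordinate in column ", col, " at row ", bad[1])
    df[[col]] <- v
  }
  df$label <- normalize_grade(df$label)
  split(df[, c("x_min", "y_min", "x_max", "y_max", "label")],
        factor(df$filename, levels = unique(df$filename)))
}

#' @rdname read_annotations_csv
#' @param samples List of [koa_sample()] objects.
#' @export
write_annotations_csv <- function(samples, path) {
  rows <- lapply(samples, function(s) {
    if (!nrow(s$annotations)) return(NULL)
    cbind(filename = paste0(s$id, ".png"), s$annotations)
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df))
    df <- data.frame(filename = character(0), x_min = numeric(0),
                     y_min = numeric(0), x_max = numeric(0),
                     y_max = numeric(0), label = character(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Per class, `floor(ratio * n)` samples go to the training set (selection
#' by a seeded shuffle) and the remainder to the test set; this floor rule
#' is what reproduces the published per-grade 8:2 composition exactly.
#'
#' @param labels Class label per sample.
#' @param ratio Training fraction in (0, 1).
#' @param seed Shuffle seed.
#' @return List with `train` and `test` index vectors and a `counts` data
#'   frame (per-class train/test/total).
#' @export
stratified_split <- function(labels, ratio = 0.8, seed = 1) {
  stopifnot(ratio > 0, ratio < 1)
  labels <- as.character(labels)
  train <- integer(0); test <- integer(0)
  classes <- unique(labels)
  counts <- data.frame(class = classes, train = 0L, test = 0L, total = 0L)
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    n_train <- as.integer(floor(ratio * length(idx)))
    perm <- with_seed(seed + ci, sample(idx))
    train <- c(train, sort(perm[seq_len(n_train)]))
    test <- c(test, sort(perm[-seq_len(n_train)]))
    counts$train[ci] <- n_train
    counts$test[ci] <- length(idx) - n_train
    counts$total[ci] <- length(idx)
  }
  list(train = sort(train), test = sort(test), counts = counts)
}

# nearest-neighbour rotation about the image center (background 0)
.rotate_matrix <- function(m, theta_deg) {
  h <- nrow(m); w <- ncol(m)
  th <- theta_deg * pi / 180
  ci <- (h + 1) / 2; cj <- (w + 1) / 2
  grid <- expand.grid(i = seq_len(h), j = seq_len(w))
  di <- grid$i - ci; dj <- grid$j - cj
  si <- round(cos(th) * di + sin(th) * dj + ci)
  sj <- round(-sin(th) * di + cos(th) * dj + cj)
  ok <- si >= 1 & si <= h & sj >= 1 & sj <= w
  out <- matrix(0, h, w)
  out[cbind(grid$i[ok], grid$j[ok])] <- m[cbind(si[ok], sj[ok])]
  out
}

.rotate_boxes <- function(ann, theta_deg, h, w) {
  if (!nrow(ann)) return(ann)
  th <- theta_deg * pi / 180
  cx <- w / 2; cy <- h / 2
  for (k in seq_len(nrow(ann))) {
    xs <- c(ann$x_min[k], ann$x_max[k])
    ys <- c(ann$y_min[k], ann$y_max[k])
    corners <- expand.grid(x = xs, y = ys)
    # forward map matching the pixel rotation (rotation about the center)
    rx <- cos(th) * (corners$x - cx) - sin(th) * (corners$y - cy) + cx
    ry <- sin(th) * (corners$x - cx) + cos(th) * (corners$y - cy) + cy
    ann$x_min[k] <- max(min(rx), 0); ann$x_max[k] <- min(max(rx), w)
    ann$y_min[k] <- max(min(ry), 0); ann$y_max[k] <- min(max(ry), h)
  }
  ann
}

#' Augment a sample
#'
#' Runtime augmentation: horizontal flip (mirrors pixels, remaps boxes as
#' `x -> W - x`), rotation by a uniform angle in `[-range, +range]` degrees
#' (boxes become the clipped axis-aligned hull of their rotated corners),
#' and random cropping (boxes survive when their center lies inside the
#' crop; a crop that would drop every box is retried and finally gives back
#' the unaugmented sample). Deterministic under a fixed seed.
#'
#' @param sample A [koa_sample()].
#' @param ops Subset of `c("hflip", "rotate", "random_crop")`.
#' @param seed RNG seed.
#' @param rotate_range Maximum absolute rotation in degrees (default 15).
#' @param crop_fraction Minimum kept fraction per dimension (default 0.8).
#' @param max_retries Crop retries before giving up.
#' @return The augmented `koa_sample`.
#' @export
augment_sample <- function(sample, ops = c("hflip", "rotate", "random_crop"),
                           seed = 1, rotate_range = 15, crop_fraction = 0.8,
                           max_retries = 10) {
  bad <- setdiff(ops, c("hflip", "rotate", "random_crop"))
  if (length(bad)) stop("unknown augmentation op(s): ",
                        paste(bad, collapse = ", "))
  with_seed(seed, {
    img <- sample$image
    ann <- sample$annotations
    if ("hflip" %in% ops) {
      w <- ncol(img)
      img <- img[, rev(seq_len(w)), drop = FALSE]
      if (nrow(ann)) {
        x0 <- ann$x_min
        ann$x_min <- w - ann$x_max
        ann$x_max <- w - x0
      }
    }
    if ("rotate" %in% ops) {
      theta <- stats::runif(1, -rotate_range, rotate_range)
      if (abs(theta) > 1e-12) {
        ann <- .rotate_boxes(ann, theta, nrow(img), ncol(img))
        img <- .rotate_matrix(img, theta)
      }
    }
    if ("random_crop" %in% ops) {
      h <- nrow(img); w <- ncol(img)
      done <- FALSE
      for (r in seq_len(max_retries)) {
        ch <- round(stats::runif(1, crop_fraction, 1) * h)
        cw <- round(stats::runif(1, crop_fraction, 1) * w)
        i0 <- floor(stats::runif(1, 0, h - ch + 1))
        j0 <- floor(stats::runif(1, 0, w - cw + 1))
        if (nrow(ann)) {
          cx <- (ann$x_min + ann$x_max) / 2
          cy <- (ann$y_min + ann$y_max) / 2
          keep <- cx > j0 & cx < j0 + cw & cy > i0 & cy < i0 + ch
          if (!any(keep)) next
          ann2 <- ann[keep, , drop = FALSE]
          ann2$x_min <- pmax(ann2$x_min - j0, 0)
          ann2$x_max <- pmin(ann2$x_max - j0, cw)
          ann2$y_min <- pmax(ann2$y_min - i0, 0)
          ann2$y_max <- pmin(ann2$y_max - i0, ch)
          ann <- ann2
        }
        img <- img[(i0 + 1):(i0 + ch), (j0 + 1):(j0 + cw), drop = FALSE]
        done <- TRUE
        break
      }
      if (!done) return(sample)
    }
    koa_sample(img, sample$id, ann)
  })
}
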