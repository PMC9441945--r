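# Annotation containers and I/O.
#
# Coordinate convention, used everywhere in the package: pixel xyxy, origin
# at the top-left corner, 0-based, half-open [x1, x2) x [y1, y2); images are
# numeric arrays (H, W, 3) in [0, 1].

default_classes <- function() c("healthy", "rust", "scab", "black_rot")

#' An annotated image
#'
#' @param image numeric `(H, W, 3)` array in \[0, 1\], or `NULL` when only
#'   the annotation (plus `width`/`height`) is carried.
#' @param boxes numeric n x 4 matrix of pixel `x1, y1, x2, y2`.
#' @param class_ids integer vector (0-based), one per box.
#' @param source_id identifier used for file naming and ordering.
#' @param width,height image dimensions in pixels (derived from `image` when
#'   present).
#' @return object of class `annotated_image`.
#' @export
annotated_image <- function(image = NULL, boxes = matrix(0, 0, 4),
                            class_ids = integer(), source_id = "img",
                            width = NULL, height = NULL) {
  boxes <- matrix(as.numeric(boxes), ncol = 4)
  if (nrow(boxes) != length(class_ids))
    stop("boxes and class_ids lengths differ")
  if (!is.null(image)) {
    height <- dim(image)[1]
    width <- dim(image)[2]
  }
  if (nrow(boxes) > 0) {
    clip <- pmin(pmax(boxes, 0), rep(c(width, height, width, height),
                                     each = nrow(boxes)))
    if (any(abs(clip - boxes) > 1e-6))
      warning("boxes outside image bounds clipped: ", source_id)
    boxes <- clip
  }
  structure(list(image = image, boxes = boxes,
                 class_ids = as.integer(class_ids),
                 source_id = as.character(source_id),
                 width = width, height = height),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image> %s  %dx%d  %d box(es)\n", x$source_id,
              x$width %||% NA, x$height %||% NA, nrow(x$boxes)))
  invisible(x)
}

#' Read bounding-box annotations
#'
#' Supports the three interchange formats of the field.  All are normalised
#' on loading to pixel xyxy with 0-based class ids; out-of-bounds boxes are
#' clipped with a warning; an image with an empty label file is a valid
#' negative sample.  Expected layouts: YOLO — `root/images/*.png` +
#' `root/labels/*.txt` with lines `cls cx cy w h` (normalised);
#' VOC — `root/images/*.png` + `root/annotations/*.xml`;
#' COCO — `root/images/*.png` + `root/annotations.json`.
#'
#' @param root dataset directory.
#' @param format `"yolo_txt"`, `"voc_xml"` or `"coco_json"`.
#' @param classes class-name vector fixing the name-to-id mapping.
#' @param load_images read pixel data (otherwise only sizes and boxes).
#' @return list of [annotated_image()] objects ordered by `source_id`.
#' @export
read_annotations <- function(root, format = c("yolo_txt", "voc_xml",
                                              "coco_json"),
                             classes = default_classes(),
                             load_images = FALSE) {
  format <- match.arg(format)
  out <- switch(format,
    yolo_txt = read_yolo_txt(root, classes),
    voc_xml = read_voc_xml(root, classes),
    coco_json = read_coco_json(root, classes))
  out <- out[order(vapply(out, `[[`, "", "source_id"))]
  if (load_images)
    out <- lapply(out, function(ai) {
      ai$image <- read_image(file.path(root, "images",
                                       paste0(ai$source_id, ".png")))
      ai
    })
  out
}

read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
}

png_size <- function(path) {
  d <- dim(png::readPNG(path))
  c(height = d[1], width = d[2])
}

read_yolo_txt <- function(root, classes) {
  imgs <- sort(list.files(file.path(root, "images"), pattern = "\\.png$"))
  lapply(imgs, function(f) {
    id <- sub("\\.png$", "", f)
    sz <- png_size(file.path(root, "images", f))
    lab <- file.path(root, "labels", paste0(id, ".txt"))
    boxes <- matrix(0, 0, 4)
    cls <- integer()
    if (file.exists(lab) && file.size(lab) > 0) {
      lines <- readLines(lab, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      for (li in seq_along(lines)) {
        v <- suppressWarnings(as.numeric(strsplit(trimws(lines[li]),
                                                  "\\s+")[[1]]))
        if (length(v) != 5 || any(is.na(v)))
          stop("malformed YOLO record at ", lab, " line ", li)
        cx <- v[2] * sz["width"]; cy <- v[3] * sz["height"]
        w <- v[4] * sz["width"]; h <- v[5] * sz["height"]
        boxes <- rbind(boxes, c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2))
        cls <- c(cls, as.integer(v[1]))
      }
    }
    annotated_image(boxes = boxes, class_ids = cls, source_id = id,
                    width = unname(sz["width"]), height = unname(sz["height"]))
  })
}

read_voc_xml <- function(root, classes) {
  xmls <- sort(list.files(file.path(root, "annotations"), pattern = "\\.xml$",
                          full.names = TRUE))
  lapply(xmls, function(f) {
    doc <- xml2::read_xml(f)
    id <- sub("\\.(png|jpg)$", "",
              xml2::xml_text(xml2::xml_find_first(doc, "./filename")))
    w <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/width")))
    h <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, "./size/height")))
    objs <- xml2::xml_find_all(doc, "./object")
    boxes <- matrix(0, 0, 4)
    cls <- integer()
    for (o in objs) {
      nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
      ci <- match(nm, classes) - 1L
      if (is.na(ci)) stop("unknown class '", nm, "' in ", f)
      bb <- vapply(c("xmin", "ymin", "xmax", "ymax"), function(k)
        as.numeric(xml2::xml_text(xml2::xml_find_first(o,
                                                       paste0("./bndbox/", k)))),
        numeric(1))
      boxes <- rbind(boxes, bb)
      cls <- c(cls, ci)
    }
    annotated_image(boxes = boxes, class_ids = cls, source_id = id,
                    width = w, height = h)
  })
}

read_coco_json <- function(root, classes) {
  path <- file.path(root, "annotations.json")
  if (!file.exists(path)) stop("COCO annotation file not found: ", path)
  j <- jsonlite::read_json(path)
  cat_map <- vapply(j$categories, function(c) c$id, numeric(1))
  cat_cls <- vapply(j$categories, function(c)
    match(c$name, classes) - 1L, integer(1))
  lapply(j$images, function(im) {
    anns <- Filter(function(a) a$image_id == im$id, j$annotations)
    boxes <- matrix(0, 0, 4)
    cls <- integer()
    for (a in anns) {
      bb <- as.numeric(unlist(a$bbox))  # x, y, w, h
      boxes <- rbind(boxes, c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4]))
      cls <- c(cls, cat_cls[match(a$category_id, cat_map)])
    }
    annotated_image(boxes = boxes, class_ids = cls,
                    source_id = sub("\\.png$", "", im$file_name),
                    width = im$width, height = im$height)
  })
}

#' Write bounding-box annotations
#'
#' Inverse of [read_annotations()]: emits standard-conformant files in the
#' chosen format (and the pixel data as PNG when present).  Output ordering
#' is deterministic by `source_id`; read-after-write recovers the input up to
#' coordinate rounding (at most one pixel for the normalised YOLO format).
#'
#' @param data list of [annotated_image()] objects.
#' @param root output directory (created if needed).
#' @param format,classes as in [read_annotations()].
#' @return `root`, invisibly.
#' @export
write_annotations <- function(data, root, format = c("yolo_txt", "voc_xml",
                                                     "coco_json"),
                              classes = default_classes()) {
  format <- match.arg(format)
  data <- data[order(vapply(data, `[[`, "", "source_id"))]
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  for (ai in data)
    if (!is.null(ai$image))
      write_image(ai$image, file.path(root, "images",
                                      paste0(ai$source_id, ".png")))
  switch(format,
    yolo_txt = {
      dir.create(file.path(root, "labels"), showWarnings = FALSE)
      for (ai in data) {
        lines <- character(nrow(ai$boxes))
        for (i in seq_len(nrow(ai$boxes))) {
          b <- ai$boxes[i, ]
          lines[i] <- sprintf("%d %.6f %.6f %.6f %.6f", ai$class_ids[i],
                              (b[1] + b[3]) / 2 / ai$width,
                              (b[2] + b[4]) / 2 / ai$height,
                              (b[3] - b[1]) / ai$width,
                              (b[4] - b[2]) / ai$height)
        }
        writeLines(lines, file.path(root, "labels",
                                    paste0(ai$source_id, ".txt")))
      }
    },
    voc_xml = {
      dir.create(file.path(root, "annotations"), showWarnings = FALSE)
      for (ai in data) {
        doc <- xml2::xml_new_root("annotation")
        xml2::xml_add_child(doc, "filename", paste0(ai$source_id, ".png"))
        sz <- xml2::xml_add_child(doc, "size")
        xml2::xml_add_child(sz, "width", as.character(ai$width))
        xml2::xml_add_child(sz, "height", as.character(ai$height))
        xml2::xml_add_child(sz, "depth", "3")
        for (i in seq_len(nrow(ai$boxes))) {
          o <- xml2::xml_add_child(doc, "object")
          xml2::xml_add_child(o, "name", classes[ai$class_ids[i] + 1])
          bb <- xml2::xml_add_child(o, "bndbox")
          xml2::xml_add_child(bb, "xmin", format(ai$boxes[i, 1]))
          xml2::xml_add_child(bb, "ymin", format(ai$boxes[i, 2]))
          xml2::xml_add_child(bb, "xmax", format(ai$boxes[i, 3]))
          xml2::xml_add_child(bb, "ymax", format(ai$boxes[i, 4]))
        }
        xml2::write_xml(doc, file.path(root, "annotations",
                                       paste0(ai$source_id, ".xml")))
      }
    },
    coco_json = {
      images <- list()
      anns <- list()
      aid <- 0
      for (k in seq_along(data)) {
        ai <- data[[k]]
        images[[k]] <- list(id = k, file_name = paste0(ai$source_id, ".png"),
                            width = ai$width, height = ai$height)
        for (i in seq_len(nrow(ai$boxes))) {
          aid <- aid + 1
          b <- ai$boxes[i, ]
          anns[[aid]] <- list(id = aid, image_id = k,
                              category_id = ai$class_ids[i] + 1,
                              bbox = c(b[1], b[2], b[3] - b[1], b[4] - b[2]),
                              area = (b[3] - b[1]) * (b[4] - b[2]),
                              iscrowd = 0)
        }
      }
      cats <- lapply(seq_along(classes), function(i)
        list(id = i, name = classes[i]))
      jsonlite::write_json(list(images = images, annotations = anns,
                                categories = cats),
                           file.path(root, "annotations.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  invisible(root)
}

#' Letterbox an image to a stride-compatible size
#'
#' Aspect-preserving resize so the long side equals `target`, then pad the
#' short side with constant grey up to the next multiple of `stride`.
#'
#' @param img `(H, W, 3)` array.
#' @param target long-side length (must itself be a stride multiple).
#' @param stride pad granularity.
#' @param fill padding intensity.
#' @return list `image`, `scale`, `pad` (c(dx, dy)); use
#'   [letterbox_boxes()] / [letterbox_invert()] to map coordinates.
#' @export
letterbox <- function(img, target, stride = 32, fill = 0.447) {
  if (target %% stride != 0) stop("target must be divisible by stride")
  d <- dim(img)
  scale <- target / max(d[1], d[2])
  nh <- round(d[1] * scale)
  nw <- round(d[2] * scale)
  resized <- resize_nearest(img, nh, nw)
  ph <- ceiling(nh / stride) * stride
  pw <- ceiling(nw / stride) * stride
  dy <- (ph - nh) %/% 2
  dx <- (pw - nw) %/% 2
  out <- array(fill, c(ph, pw, 3))
  out[dy + seq_len(nh), dx + seq_len(nw), ] <- resized
  list(image = out, scale = scale, pad = c(dx = dx, dy = dy))
}

#' @rdname letterbox
#' @param boxes n x 4 pixel xyxy matrix in source coordinates.
#' @param lb the list returned by `letterbox()`.
#' @export
letterbox_boxes <- function(boxes, lb) {
  if (nrow(boxes) == 0) return(boxes)
  cbind(boxes[, 1] * lb$scale + lb$pad["dx"],
        boxes[, 2] * lb$scale + lb$pad["dy"],
        boxes[, 3] * lb$scale + lb$pad["dx"],
        boxes[, 4] * lb$scale + lb$pad["dy"])
}

#' @rdname letterbox
#' @export
letterbox_invert <- function(boxes, lb) {
  if (nrow(boxes) == 0) return(boxes)
  cbind((boxes[, 1] - lb$pad["dx"]) / lb$scale,
        (boxes[, 2] - lb$pad["dy"]) / lb$scale,
        (boxes[, 3] - lb$pad["dx"]) / lb$scale,
        (boxes[, 4] - lb$pad["dy"]) / lb$scale)
}

resize_nearest <- function(img, nh, nw) {
  d <- dim(img)
  ri <- pmin(pmax(round((seq_len(nh) - 0.5) * d[1] / nh + 0.5), 1), d[1])
  ci <- pmin(pmax(round((seq_len(nw) - 0.5) * d[2] / nw + 0.5), 1), d[2])
  img[ri, ci, , drop = FALSE]
}

# ---- augmentation --------------------------------------------------------

#' Augmentation configuration
#'
#' Photometric gains and geometric magnitudes follow the usual one-stage
#' detector defaults: HSV jitter (0.015, 0.7, 0.4), translation 0.1 of the
#' canvas, scale 0.5, no shear/rotation, horizontal flip with probability
#' 0.5.
#'
#' @param hsv_h,hsv_s,hsv_v HSV jitter gains.
#' @param degrees,translate,scale,shear affine magnitudes.
#' @param fliplr_prob probability of horizontal flip.
#' @param mosaic use 4-image mosaic in pipelines that support it.
#' @param seed RNG seed.
#' @return an `augment_config` list.
#' @export
augment_config <- function(hsv_h = 0.015, hsv_s = 0.7, hsv_v = 0.4,
                           degrees = 0, translate = 0.1, scale = 0.5,
                           shear = 0, fliplr_prob = 0.5, mosaic = TRUE,
                           seed = 0) {
  stopifnot(fliplr_prob >= 0, fliplr_prob <= 1, hsv_h >= 0, hsv_s >= 0,
            hsv_v >= 0)
  structure(list(hsv_h = hsv_h, hsv_s = hsv_s, hsv_v = hsv_v,
                 degrees = degrees, translate = translate, scale = scale,
                 shear = shear, fliplr_prob = fliplr_prob, mosaic = mosaic,
                 seed = seed),
            class = "augment_config")
}

# vectorised HSV -> RGB on 3 x n matrices with h, s, v in [0, 1]
hsv_to_rgb <- function(hsv) {
  h <- (hsv[1, ] %% 1) * 6
  s <- pmin(pmax(hsv[2, ], 0), 1)
  v <- pmin(pmax(hsv[3, ], 0), 1)
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  rbind(r, g, b)
}

hsv_jitter <- function(img, gains) {
  d <- dim(img)
  M <- t(matrix(img, d[1] * d[2], 3))
  hsv <- grDevices::rgb2hsv(M, maxColorValue = 1)
  hsv[1, ] <- hsv[1, ] + gains[1]
  hsv[2, ] <- hsv[2, ] * gains[2]
  hsv[3, ] <- hsv[3, ] * gains[3]
  array(t(hsv_to_rgb(hsv)), d)
}

#' Augment an annotated image
#'
#' Photometric HSV jitter (boxes untouched) followed by a random affine
#' (rotation, translation, scale, shear about the canvas centre) and a
#' horizontal flip; boxes are mapped through the same affine, clipped to the
#' canvas and dropped together with their labels when they degenerate below
#' 2 px on a side.  Deterministic for a fixed `seed`.
#'
#' @param item an [annotated_image()] with pixel data.
#' @param cfg an [augment_config()].
#' @param seed overrides `cfg$seed`.
#' @return the augmented `annotated_image`.
#' @export
augment_image <- function(item, cfg = augment_config(), seed = cfg$seed) {
  set.seed(seed)
  img <- item$image
  d <- dim(img)
  g <- c(stats::runif(1, -cfg$hsv_h, cfg$hsv_h),
         1 + stats::runif(1, -cfg$hsv_s, cfg$hsv_s),
         1 + stats::runif(1, -cfg$hsv_v, cfg$hsv_v))
  if (cfg$hsv_h + cfg$hsv_s + cfg$hsv_v > 0) img <- hsv_jitter(img, g)
  ang <- stats::runif(1, -cfg$degrees, cfg$degrees) * pi / 180
  sc <- 1 + stats::runif(1, -cfg$scale, cfg$scale)
  shx <- tan(stats::runif(1, -cfg$shear, cfg$shear) * pi / 180)
  tx <- stats::runif(1, -cfg$translate, cfg$translate) * d[2]
  ty <- stats::runif(1, -cfg$translate, cfg$translate) * d[1]
  flip <- stats::runif(1) < cfg$fliplr_prob
  A <- affine_matrix(d, ang, sc, shx, tx, ty, flip)
  if (any(abs(A - diag(3)[1:2, ]) > 1e-12)) {
    img <- warp_affine(img, A)
    boxes <- transform_boxes(item$boxes, A)
    keep <- clip_and_filter(boxes, d[2], d[1])
    out <- annotated_image(img, keep$boxes, item$class_ids[keep$keep],
                           item$source_id)
  } else {
    out <- annotated_image(img, item$boxes, item$class_ids, item$source_id)
  }
  out
}

affine_matrix <- function(d, ang, sc, shx, tx, ty, flip) {
  cx <- d[2] / 2
  cy <- d[1] / 2
  # forward map: centre -> rotate/scale/shear -> un-centre -> translate
  R <- matrix(c(sc * cos(ang), -sc * sin(ang),
                sc * sin(ang), sc * cos(ang)), 2, 2, byrow = TRUE)
  S <- matrix(c(1, shx, 0, 1), 2, 2, byrow = TRUE)
  F <- if (flip) matrix(c(-1, 0, 0, 1), 2, 2) else diag(2)
  M <- R %*% S %*% F
  off <- c(cx + tx, cy + ty) - M %*% c(cx, cy)
  cbind(M, off)  # 2 x 3 acting on (x, y, 1)
}

warp_affine <- function(img, A, fill = 0.447) {
  d <- dim(img)
  Ainv <- solve(rbind(A, c(0, 0, 1)))[1:2, ]
  xs <- rep(seq_len(d[2]) - 0.5, each = d[1])
  ys <- rep(seq_len(d[1]) - 0.5, times = d[2])
  sx <- Ainv[1, 1] * xs + Ainv[1, 2] * ys + Ainv[1, 3]
  sy <- Ainv[2, 1] * xs + Ainv[2, 2] * ys + Ainv[2, 3]
  ci <- round(sx + 0.5)
  ri <- round(sy + 0.5)
  ok <- ci >= 1 & ci <= d[2] & ri >= 1 & ri <= d[1]
  out <- array(fill, d)
  src <- cbind(ri[ok], ci[ok])
  dst <- which(ok)
  for (ch in 1:3) {
    plane <- img[, , ch]
    o <- matrix(fill, d[1], d[2])
    o[dst] <- plane[src]
    out[, , ch] <- o
  }
  out
}

transform_boxes <- function(boxes, A) {
  if (nrow(boxes) == 0) return(boxes)
  t(apply(boxes, 1, function(b) {
    xs <- c(b[1], b[3], b[1], b[3])
    ys <- c(b[2], b[2], b[4], b[4])
    nx <- A[1, 1] * xs + A[1, 2] * ys + A[1, 3]
    ny <- A[2, 1] * xs + A[2, 2] * ys + A[2, 3]
    c(min(nx), min(ny), max(nx), max(ny))
  }))
}

clip_and_filter <- function(boxes, w, h, min_size = 2) {
  if (nrow(boxes) == 0) return(list(boxes = boxes, keep = logical(0)))
  boxes[, c(1, 3)] <- pmin(pmax(boxes[, c(1, 3)], 0), w)
  boxes[, c(2, 4)] <- pmin(pmax(boxes[, c(2, 4)], 0), h)
  keep <- (boxes[, 3] - boxes[, 1]) >= min_size &
    (boxes[, 4] - boxes[, 2]) >= min_size
  list(boxes = boxes[keep, , drop = FALSE], keep = keep)
}

#' Mosaic augmentation
#'
#' Combines four annotated images into one collage: a 2 x 2 arrangement on a
#' double-size canvas around a centre drawn uniformly from the central half,
#' each tile letterbox-scaled to the canvas size; boxes are remapped and
#' clipped, then the collage is passed through [augment_image()] (when `cfg`
#' is supplied).  Clipping may drop boxes, so the output label count never
#' exceeds the sum of the inputs.
#'
#' @param items list of exactly four [annotated_image()] objects with pixels.
#' @param canvas tile edge length; the collage is `2 * canvas` square.
#' @param cfg optional [augment_config()] applied to the collage.
#' @param seed RNG seed.
#' @return an `annotated_image` of size `2*canvas` x `2*canvas`.
#' @export
mosaic4 <- function(items, canvas, cfg = NULL, seed = 0) {
  if (length(items) != 4) stop("mosaic4 needs exactly 4 images")
  set.seed(seed)
  S <- canvas
  cx <- round(stats::runif(1, 0.5 * S, 1.5 * S))
  cy <- round(stats::runif(1, 0.5 * S, 1.5 * S))
  out <- array(0.447, c(2 * S, 2 * S, 3))
  boxes <- matrix(0, 0, 4)
  cls <- integer()
  # tile regions: top-left, top-right, bottom-left, bottom-right
  for (i in 1:4) {
    lb <- letterbox(items[[i]]$image, S, stride = S)
    tile <- lb$image
    tb <- letterbox_boxes(items[[i]]$boxes, lb)
    x0 <- if (i %% 2 == 1) cx - S else cx
    y0 <- if (i <= 2) cy - S else cy
    xs <- max(x0, 0):min(x0 + S - 1, 2 * S - 1)
    ys <- max(y0, 0):min(y0 + S - 1, 2 * S - 1)
    if (length(xs) == 0 || length(ys) == 0) next
    out[ys + 1, xs + 1, ] <- tile[ys - y0 + 1, xs - x0 + 1, , drop = FALSE]
    if (nrow(tb) > 0) {
      tb[, c(1, 3)] <- tb[, c(1, 3)] + x0
      tb[, c(2, 4)] <- tb[, c(2, 4)] + y0
      boxes <- rbind(boxes, tb)
      cls <- c(cls, items[[i]]$class_ids)
    }
  }
  kf <- clip_and_filter(boxes, 2 * S, 2 * S)
  res <- annotated_image(out, kf$boxes, cls[kf$keep],
                         paste0("mosaic_", items[[1]]$source_id))
  if (!is.null(cfg)) res <- augment_image(res, cfg, seed = seed + 1)
  res
}
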