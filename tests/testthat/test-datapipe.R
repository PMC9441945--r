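test_that("YOLO-txt denormalisation follows the stated arithmetic", {
  td <- tempfile()
  dir.create(file.path(td, "images"), recursive = TRUE)
  dir.create(file.path(td, "labels"))
  png::writePNG(array(0.5, c(640, 640, 3)), file.path(td, "images", "a.png"))
  writeLines("1 0.5 0.5 0.5 0.5", file.path(td, "labels", "a.txt"))
  ai <- read_annotations(td, "yolo_txt")[[1]]
  expect_equal(unname(ai$boxes[1, ]), c(160, 160, 480, 480))
  expect_equal(ai$class_ids, 1L)  # rust
  # empty label file is a valid negative, not an error
  png::writePNG(array(0.5, c(64, 64, 3)), file.path(td, "images", "b.png"))
  writeLines(character(0), file.path(td, "labels", "b.txt"))
  items <- read_annotations(td, "yolo_txt")
  expect_equal(nrow(items[[2]]$boxes), 0)
  # malformed record names file and line
  writeLines("1 0.5 oops", file.path(td, "labels", "b.txt"))
  expect_error(read_annotations(td, "yolo_txt"), "line 1")
})

test_that("annotations round-trip through all three formats", {
  set.seed(21)
  items <- lapply(1:4, function(i) generate_scene(scene_spec(canvas = 96),
                                                  seed = 20 + i))
  for (fmt in c("yolo_txt", "voc_xml", "coco_json")) {
    td <- file.path(tempfile(), fmt)
    write_annotations(items, td, fmt)
    back <- read_annotations(td, fmt)
    expect_length(back, length(items))
    for (k in seq_along(items)) {
      expect_equal(back[[k]]$source_id, items[[k]]$source_id)
      expect_equal(back[[k]]$class_ids, items[[k]]$class_ids, info = fmt)
      if (nrow(items[[k]]$boxes) > 0)
        expect_lt(max(abs(back[[k]]$boxes - items[[k]]$boxes)), 1,
                  label = paste(fmt, "drift"))
    }
  }
  # COCO output carries the standard top-level keys
  td <- file.path(tempfile(), "coco")
  write_annotations(items, td, "coco_json")
  j <- jsonlite::read_json(file.path(td, "annotations.json"))
  expect_true(all(c("images", "annotations", "categories") %in% names(j)))
})

test_that("letterbox scales the long side and pads to a stride multiple", {
  img <- array(runif(1280 * 720 * 3), c(720, 1280, 3))
  lb <- letterbox(img, 640, stride = 64)
  expect_equal(dim(lb$image)[2], 640)       # long side
  expect_equal(dim(lb$image)[1], 384)       # 360 padded to next 64-multiple
  # square input gets zero padding
  sq <- letterbox(array(0.3, c(100, 100, 3)), 128, stride = 32)
  expect_equal(unname(sq$pad), c(0, 0))
  # forward + inverse box mapping is the identity within half a pixel
  b <- matrix(c(100, 50, 600, 700, 300, 200, 900, 650), 2, byrow = TRUE)
  expect_lt(max(abs(letterbox_invert(letterbox_boxes(b, lb), lb) - b)), 0.5)
  expect_error(letterbox(img, 100, stride = 64), "divisible")
})

test_that("photometric augmentation leaves geometry untouched", {
  sc <- generate_scene(scene_spec(canvas = 96), seed = 31)
  cfg <- augment_config(degrees = 0, translate = 0, scale = 0, shear = 0,
                        fliplr_prob = 0)
  out <- augment_image(sc, cfg, seed = 5)
  expect_equal(out$boxes, sc$boxes)
  expect_equal(out$class_ids, sc$class_ids)
  expect_false(identical(out$image, sc$image))
  # identity config reproduces the input exactly
  ident <- augment_config(0, 0, 0, 0, 0, 0, 0, fliplr_prob = 0)
  expect_equal(augment_image(sc, ident, seed = 5)$image, sc$image)
  # fixed seed -> identical output
  expect_identical(augment_image(sc, cfg, seed = 5),
                   augment_image(sc, cfg, seed = 5))
})

test_that("horizontal flip maps boxes by x -> W - x", {
  img <- array(0.5, c(640, 640, 3))
  ai <- annotated_image(img, matrix(c(10, 10, 20, 20), 1), 0L, "f")
  cfg <- augment_config(0, 0, 0, 0, 0, 0, 0, fliplr_prob = 1)
  out <- augment_image(ai, cfg, seed = 1)
  expect_equal(unname(out$boxes[1, ]), c(620, 10, 630, 20))
  expect_equal(out$class_ids, 0L)
})

test_that("geometric augmentation keeps class ids attached to their boxes", {
  sc <- generate_scene(scene_spec(canvas = 128, n_leaves = c(3, 3)), seed = 8)
  cfg <- augment_config(0, 0, 0, degrees = 5, translate = 0.05, scale = 0.2,
                        shear = 2, fliplr_prob = 0.5)
  out <- augment_image(sc, cfg, seed = 2)
  expect_equal(nrow(out$boxes), length(out$class_ids))
  expect_lte(nrow(out$boxes), nrow(sc$boxes))
  expect_true(all(out$boxes[, c(1, 3)] >= 0 & out$boxes[, c(1, 3)] <= 128))
})

test_that("mosaic composes four images and conserves or drops labels", {
  items <- lapply(1:4, function(i)
    generate_scene(scene_spec(canvas = 96, n_leaves = c(1, 1)), seed = 40 + i))
  mo <- mosaic4(items, canvas = 96, seed = 3)
  expect_equal(dim(mo$image), c(192, 192, 3))
  expect_lte(nrow(mo$boxes), sum(vapply(items, function(x) nrow(x$boxes), 0L)))
  expect_true(all(mo$boxes >= 0 & mo$boxes <= 192))
  expect_identical(mosaic4(items, canvas = 96, seed = 3), mo)
  expect_error(mosaic4(items[1:3], 96), "exactly 4")
})
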