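test_that("scene generation is deterministic and respects its contract", {
  spec <- scene_spec(canvas = 128, n_leaves = c(3, 3))
  a <- generate_scene(spec, seed = 7)
  b <- generate_scene(spec, seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
  expect_identical(a$class_ids, b$class_ids)
  expect_equal(nrow(a$boxes), 3)
  expect_true(all(a$boxes >= 0 & a$boxes <= 128))
  expect_true(all((a$boxes[, 3] - a$boxes[, 1]) > 0))
  expect_true(all(a$class_ids %in% 0:3))
  expect_error(scene_spec(canvas = 32), "too small")
})

test_that("lesion phenotypes make classes separable by colour", {
  # mean hue inside the box should separate rust (orange) from scab (olive)
  # and black rot (brown rings) from healthy (plain green)
  spec <- scene_spec(canvas = 160, n_leaves = c(1, 1))
  feats <- t(vapply(0:19, function(i) {
    sc <- generate_scene(spec, seed = 200 + i, class_order = i %% 4)
    b <- round(sc$boxes[1, ])
    crop <- sc$image[max(b[2], 1):b[4], max(b[1], 1):b[3], ]
    M <- t(matrix(crop, ncol = 3))
    hsv <- grDevices::rgb2hsv(M, maxColorValue = 1)
    c(cls = sc$class_ids[1],
      orange = mean(hsv[1, ] < 0.12 & hsv[2, ] > 0.5 & hsv[3, ] > 0.5),
      dark = mean(hsv[3, ] < 0.28))
  }, numeric(3)))
  orange_rust <- feats[feats[, 1] == 1, "orange"]
  orange_other <- feats[feats[, 1] != 1, "orange"]
  expect_gt(min(orange_rust), max(orange_other))
  dark_scab <- feats[feats[, 1] == 2, "dark"]
  dark_healthy <- feats[feats[, 1] == 0, "dark"]
  expect_gt(min(dark_scab), max(dark_healthy))
})

test_that("dataset generation writes balanced, reproducible splits", {
  td <- tempfile()
  man <- generate_dataset(26, scene_spec(canvas = 96), td, seed = 1)
  expect_equal(unname(table(man$split)[c("train", "val", "test")]),
               c(14L, 6L, 6L), ignore_attr = TRUE)
  expect_true(file.exists(file.path(td, "train.txt")))
  expect_length(readLines(file.path(td, "train.txt")), 14)
  # class balance: per-class label counts within 10% of each other (the
  # classes are drawn from one global cycling pool)
  counts <- colSums(man[, 3:6])
  expect_lt((max(counts) - min(counts)) / max(counts), 0.10)
  expect_gte(min(counts), 1)
  # regeneration under the same seed gives identical manifests
  td2 <- tempfile()
  man2 <- generate_dataset(26, scene_spec(canvas = 96), td2, seed = 1)
  expect_identical(man, man2)
  # annotations survive the write/read cycle
  back <- read_annotations(td, "yolo_txt")
  expect_length(back, 26)
  expect_error(generate_dataset(10, scene_spec(96), tempfile(),
                                split = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("split honours the standard 0.54/0.23/0.23 ratio at n = 100", {
  td <- tempfile()
  man <- generate_dataset(100, scene_spec(canvas = 64, n_leaves = c(1, 2)),
                          td, seed = 3)
  expect_equal(unname(table(man$split)[c("train", "val", "test")]),
               c(54L, 23L, 23L), ignore_attr = TRUE)
})
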