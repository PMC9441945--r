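test_that("model assembly follows the configuration graph", {
  m <- tiny_model("mga-yolo")
  expect_s3_class(m, "mga_model")
  expect_equal(m$strides, c(8L, 16L, 32L, 64L))
  expect_equal(m$head_channels, 27)             # 3 * (4 + 5)
  m3 <- tiny_model("yolov5s")
  expect_equal(m3$strides, c(8L, 16L, 32L))
  # class-count scaling of the head
  m80 <- build_model(mga_config("yolov5s", nc = 80, width_multiple = 0.25))
  expect_equal(m80$head_channels, 255)
  det <- m80$layers[[m80$detect_idx]]
  expect_equal(det$children$head1$c2, 255)
  # dangling from-index is a configuration error
  cfg <- mga_config("yolov5s", width_multiple = 0.25)
  cfg$head[[3]]$from <- c(-1, 99)
  expect_error(build_model(cfg), "configuration error")
})

test_that("forward produces one map per head at input/stride resolution", {
  m <- tiny_model("mga-yolo")
  x <- rand_fmap(128, 128, 3, 1, seed = 11)
  out <- model_forward(m, x)
  expect_length(out, 4)
  expect_equal(lapply(out, dim),
               list(c(16, 16, 27, 1), c(8, 8, 27, 1), c(4, 4, 27, 1),
                    c(2, 2, 27, 1)))
  # stride arithmetic at another size
  out2 <- model_forward(m, rand_fmap(192, 192, 3, 1))
  expect_equal(dim(out2[[4]])[1:2], c(3, 3))
  # indivisible input size errors, naming the required multiple
  expect_error(model_forward(m, rand_fmap(100, 100, 3, 1)), "multiple of 64")
  # eval-mode determinism
  expect_identical(out, model_forward(m, x))
})

test_that("configurations round-trip through YAML", {
  cfg <- mga_config("mga-yolo")
  path <- tempfile(fileext = ".yaml")
  write_model_config(cfg, path)
  cfg2 <- read_model_config(path)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg2)
  expect_equal(count_parameters(m1), count_parameters(m2))
  expect_equal(m2$strides, m1$strides)
  expect_error(read_model_config(tempfile()), "not found")
})

test_that("decoding inverts the head parameterisation", {
  m <- tiny_model("yolov5s", nc = 2)
  # all-zero logits: conf = sigmoid(0)^2 = 0.25, never strictly above 0.25
  zero <- lapply(seq_along(m$strides), function(h) {
    s <- m$strides[h]
    array(0, c(256 / s, 256 / s, 3 * (m$nc + 5), 1))
  })
  expect_equal(nrow(decode_predictions(zero, m, conf_thr = 0.25)), 0)
  # one hot cell decodes to one detection centred in that cell's footprint
  hot <- zero
  no <- m$nc + 5
  hot[[2]][5, 7, 5, 1] <- 10   # objectness logit, anchor 1, cell (row 5, col 7)
  hot[[2]][5, 7, 6, 1] <- 10   # class 0 logit
  dets <- decode_predictions(hot, m, conf_thr = 0.5)
  expect_equal(nrow(dets), 1)
  expect_equal(dets$class_id, 0)
  s <- m$strides[2]
  cx <- (dets$x1 + dets$x2) / 2
  cy <- (dets$y1 + dets$y2) / 2
  # sigmoid(0)*2-0.5 = 0.5 offset => centre at (cell index - 1 + 0.5) * stride
  expect_equal(cx, (7 - 1 + 0.5) * s, tolerance = 1e-9)
  expect_equal(cy, (5 - 1 + 0.5) * s, tolerance = 1e-9)
  # decoded boxes lie inside the image after clipping
  set.seed(2)
  noisy <- lapply(zero, function(z) array(rnorm(length(z), 0, 4), dim(z)))
  dd <- decode_predictions(noisy, m, conf_thr = 0.1)
  expect_true(all(dd$x1 >= 0 & dd$y1 >= 0 & dd$x2 <= 256 & dd$y2 <= 256))
  expect_error(decode_predictions(zero[1:2], m), "head maps")
})

test_that("width scaling rounds channels to multiples of 8", {
  w <- capture_warnings(
    m <- build_model(mga_config("yolov5s", width_multiple = 0.3)))
  expect_gt(length(w), 0)
  expect_true(all(grepl("rounded", w)))
  for (lay in m$layers)
    if (lay$kind %in% c("conv", "ghost_conv", "c3"))
      expect_equal(lay$c2 %% 8, 0)
  expect_warning(mgayolo:::make_divisible(100, 8), "rounded")
})
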