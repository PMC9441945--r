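test_that("learning-rate schedule hits its endpoints exactly", {
  cfg <- train_config(epochs = 100)
  expect_identical(lr_at(0, cfg), 0.01)
  expect_equal(lr_at(100, cfg), 0.01 * 0.2, tolerance = 1e-12)
  expect_equal(lr_at(50, cfg), 0.006)  # lf = 0.5 * (0.2 - 1) + 1 = 0.6
  # monotone non-increasing over the whole range for lrf < 1
  lrs <- vapply(0:100, lr_at, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) <= 1e-15))
  expect_error(lr_at(0, train_config(epochs = 0)), "positive")
  expect_error(train_config(lrf = 0), "lrf")
})

test_that("target assignment respects the anchor-ratio filter and neighbours", {
  m <- tiny_model("yolov5s", nc = 2)
  tg <- data.frame(image = 1, class_id = 0, cx = 100.2, cy = 60.7,
                   w = 40, h = 36)
  asg <- mgayolo:::build_targets(m, tg, 256)
  n_per_head <- vapply(asg, nrow, 0L)
  expect_true(sum(n_per_head) > 0)
  for (h in which(n_per_head > 0)) {
    tab <- asg[[h]]
    anc <- matrix(m$cfg$anchors[[h]], nrow = 2) / m$strides[h]
    r1 <- tab$gw / anc[1, tab$anchor]
    r2 <- tab$gh / anc[2, tab$anchor]
    expect_true(all(pmax(r1, 1 / r1, r2, 1 / r2) < 4))
    # assigned cells are the centre cell or an adjacent neighbour
    expect_true(all(abs(tab$gi + 0.5 - tab$gx) < 1.5))
    expect_true(all(abs(tab$gj + 0.5 - tab$gy) < 1.5))
  }
})

test_that("loss components behave at their floors and under misconfidence", {
  m <- tiny_model("yolov5s", nc = 2)
  dims <- lapply(m$strides, function(s)
    c(128 / s, 128 / s, 3 * (m$nc + 5), 1))
  zero <- lapply(dims, function(d) array(0, d))
  # empty target set: finite objectness-only loss
  empty <- data.frame(image = integer(), class_id = integer(), cx = numeric(),
                      cy = numeric(), w = numeric(), h = numeric())
  l0 <- compute_loss(zero, empty, m, 128)
  expect_equal(l0$box, 0)
  expect_equal(l0$cls, 0)
  expect_gt(l0$obj, 0)
  expect_true(is.finite(l0$total))
  # a confident false positive increases objectness loss monotonically
  fp <- zero
  fp[[1]][4, 4, 5, 1] <- 4
  fp2 <- zero
  fp2[[1]][4, 4, 5, 1] <- 8
  expect_gt(compute_loss(fp, empty, m, 128)$obj, l0$obj)
  expect_gt(compute_loss(fp2, empty, m, 128)$obj,
            compute_loss(fp, empty, m, 128)$obj)
  # saturated correct predictions drive box and cls toward zero
  tg <- data.frame(image = 1, class_id = 0, cx = 64, cy = 64, w = 32, h = 32)
  asg <- mgayolo:::build_targets(m, tg, 128)
  good <- zero
  for (h in seq_along(asg)) {
    tab <- asg[[h]]
    if (nrow(tab) == 0) next
    anc <- matrix(m$cfg$anchors[[h]], nrow = 2) / m$strides[h]
    no <- m$nc + 5
    for (r in seq_len(nrow(tab))) {
      ch0 <- (tab$anchor[r] - 1) * no
      # invert the decode equations for the exact cell offset and size
      offx <- tab$gx[r] - tab$gi[r]
      offy <- tab$gy[r] - tab$gj[r]
      good[[h]][tab$gj[r] + 1, tab$gi[r] + 1, ch0 + 1, 1] <-
        qlogis((offx + 0.5) / 2)
      good[[h]][tab$gj[r] + 1, tab$gi[r] + 1, ch0 + 2, 1] <-
        qlogis((offy + 0.5) / 2)
      good[[h]][tab$gj[r] + 1, tab$gi[r] + 1, ch0 + 3, 1] <-
        qlogis(sqrt(tab$gw[r] / anc[1, tab$anchor[r]]) / 2)
      good[[h]][tab$gj[r] + 1, tab$gi[r] + 1, ch0 + 4, 1] <-
        qlogis(sqrt(tab$gh[r] / anc[2, tab$anchor[r]]) / 2)
      good[[h]][tab$gj[r] + 1, tab$gi[r] + 1, ch0 + 6, 1] <- 12  # class 0
      good[[h]][tab$gj[r] + 1, tab$gi[r] + 1, ch0 + 7, 1] <- -12
    }
  }
  lg <- compute_loss(good, tg, m, 128)
  expect_lt(lg$box, 1e-6)
  expect_lt(lg$cls, 1e-4)
})

test_that("short training runs reduce the loss and log the exact schedule", {
  spec <- scene_spec(canvas = 128, n_leaves = c(1, 2))
  items <- lapply(1:8, function(i) generate_scene(spec, seed = 50 + i))
  set.seed(123)
  m <- build_model(mga_config("mga-yolo", width_multiple = 0.25))
  cfg <- train_config(epochs = 6, batch = 4, img_size = 128, seed = 1,
                      warmup_epochs = 2)
  m <- fit_model(m, items, cfg)
  expect_equal(nrow(m$log), 6)
  expect_lt(m$log$total[6], m$log$total[1])
  # after warmup the logged learning rate equals the schedule exactly
  for (e in 3:6) expect_equal(m$log$lr[e], lr_at(e - 1, cfg))
  # during warmup it ramps below the scheduled value
  expect_lt(m$log$lr[1], lr_at(0, cfg))
  # two runs with the same seed and data produce identical loss trajectories
  set.seed(123)
  m2 <- build_model(mga_config("mga-yolo", width_multiple = 0.25))
  m2 <- fit_model(m2, items, cfg)
  expect_equal(m2$log, m$log)
})
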