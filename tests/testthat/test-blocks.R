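test_that("GhostConv meets its shape contract and channel split", {
  x <- rand_fmap(32, 32, 64, 1)
  g <- mgayolo:::ghost_conv_block(64, 128, 1, 1)
  y <- blk_eval(g, x)
  expect_equal(dim(y), c(32, 32, 128, 1))
  # intrinsic half comes from the primary conv, ghost half from the cheap op
  expect_equal(g$children$primary$c2, 64)
  expect_equal(g$children$cheap$c2, 64)
  expect_equal(g$children$cheap$groups, 64)  # depthwise 5x5
  expect_equal(g$children$cheap$k, 5)
  # stride-2 downsampling halves spatial dims
  x2 <- rand_fmap(8, 8, 16, 1)
  y2 <- blk_eval(mgayolo:::ghost_conv_block(16, 16, 3, 2), x2)
  expect_equal(dim(y2), c(4, 4, 16, 1))
  expect_error(mgayolo:::ghost_conv_block(16, 15), "even")
  expect_error(blk_eval(g, rand_fmap(8, 8, 32, 1)), "shape error")
})

test_that("ghost module multiply-accumulates approach half an ordinary conv", {
  # ghost ratio s = 2: the theoretical speed-up of the cheap operations
  for (c in c(64, 128, 256)) {
    ordinary <- mgayolo:::blk_profile(mgayolo:::conv_block(c, c, 3, 1),
                                      c(32, 32))$stats["macs"]
    ghost <- mgayolo:::blk_profile(mgayolo:::ghost_conv_block(c, c, 3, 1),
                                   c(32, 32))$stats["macs"]
    expect_lt(abs(ordinary / ghost - 2), 2 * 0.15,
              label = paste("ratio at c =", c))
  }
})

test_that("GhostBottleneck preserves shape and reduces to identity at zero weights", {
  x <- rand_fmap(16, 16, 32, 1)
  gb <- mgayolo:::ghost_bottleneck_block(32, 32)
  expect_equal(dim(blk_eval(gb, x)), c(16, 16, 32, 1))
  mgayolo:::module_walk(gb, function(l) {
    l$w[] <- 0
    if (!is.null(l$b)) l$b[] <- 0
    if (l$bn) { l$gamma[] <- 0; l$beta[] <- 0 }
  })
  expect_equal(blk_eval(gb, x), x)
  expect_error(mgayolo:::ghost_bottleneck_block(32, 64), "in = out")
  # fewer parameters than an ordinary bottleneck at the same width
  expect_lt(count_parameters(mgayolo:::ghost_bottleneck_block(32, 32)),
            count_parameters(mgayolo:::bottleneck_block(32, 32)))
})

test_that("CBAM is a shape-preserving multiplicative reweighting", {
  x <- rand_fmap(8, 8, 32, 2)
  cb <- mgayolo:::cbam_block(32)
  expect_equal(dim(blk_eval(cb, x)), dim(x))
  # zero all attention logits -> each stage multiplies by sigmoid(0) = 0.5
  mgayolo:::module_walk(cb, function(l) { l$w[] <- 0; l$b[] <- 0 })
  expect_equal(blk_eval(cb, x), 0.25 * x, tolerance = 1e-12)
  # spatially uniform input -> spatially constant spatial-attention input
  xu <- array(rep(seq_len(16), each = 16), c(4, 4, 16, 1))
  cp <- mgayolo:::ag_chpool(list(v = xu), mgayolo:::ag_ctx())$v
  expect_equal(length(unique(as.vector(cp[, , 1, 1]))), 1)
  expect_equal(length(unique(as.vector(cp[, , 2, 1]))), 1)
  expect_error(mgayolo:::cbam_block(8, reduction = 16), "reduction")
})

test_that("attention variants keep shape, bounded weights, distinct parameter counts", {
  x <- rand_fmap(8, 8, 64, 1)
  counts <- numeric(0)
  for (kind in c("se", "cbam", "ca")) {
    blk <- mgayolo:::attention_block(kind, 64)
    expect_equal(dim(blk_eval(blk, x)), dim(x), info = kind)
    counts[kind] <- count_parameters(blk)
  }
  expect_true(length(unique(counts)) == 3)
  # attention weights lie in (0, 1): reweighting can only shrink magnitudes
  se <- mgayolo:::se_block(64)
  y <- blk_eval(se, x)
  expect_true(all(abs(y) <= abs(x) + 1e-12))
  expect_true(all(y * x >= 0))
})

test_that("MBConvA follows the inverted-bottleneck contract", {
  x <- rand_fmap(20, 20, 64, 1)
  mb <- mgayolo:::mbconv_block(64, 64, expansion = 1, attention = "none")
  expect_equal(dim(blk_eval(mb, x)), dim(x))
  expect_error(mgayolo:::mbconv_block(64, 64, expansion = 0.5), "expansion")
  # depthwise stage carries no activation; expansion stage does
  mb6 <- mgayolo:::mbconv_block(64, 64, 6, "cbam", act = "gelu")
  expect_equal(mb6$children$dw$act, "none")
  expect_equal(mb6$children$expand$act, "gelu")
  expect_equal(mb6$children$project$act, "none")
  expect_equal(mb6$hidden, 384)
  # zeroed projection + shortcut -> identity
  mgayolo:::module_walk(mb6$children$project, function(l) {
    l$w[] <- 0; l$gamma[] <- 0; l$beta[] <- 0
  })
  expect_equal(blk_eval(mb6, x), x)
  # swapping the attention slot changes parameters, not shape
  mse <- mgayolo:::mbconv_block(64, 64, 6, "se")
  expect_false(count_parameters(mse) == count_parameters(mb6))
  expect_equal(dim(blk_eval(mse, x)), dim(x))
})

test_that("CSP stage wires two branches and the requested inner census", {
  x <- rand_fmap(40, 40, 32, 1)
  st <- mgayolo:::csp_stage(32, 32, 1, "bottleneck")
  expect_equal(dim(blk_eval(st, x)), dim(x))
  st2 <- mgayolo:::csp_stage(32, 32, 2, "ghost_bottleneck")
  inner <- Filter(function(ch) inherits(ch, "yolo_ghost_bottleneck"),
                  st2$children)
  expect_length(inner, 2)
  expect_error(mgayolo:::csp_stage(32, 32, 1, "nope"), "unknown inner")
  expect_error(mgayolo:::csp_stage(32, 32, 0, "bottleneck"), "repeats")
  # ghost stage cheaper than plain stage at identical channels
  expect_lt(count_parameters(mgayolo:::csp_stage(64, 64, 1, "ghost_bottleneck")),
            count_parameters(mgayolo:::csp_stage(64, 64, 1, "bottleneck")))
})

test_that("residual blocks with zeroed transforms reproduce their input", {
  x <- rand_fmap(8, 8, 16, 2, seed = 5)
  makers <- list(
    function() mgayolo:::bottleneck_block(16, 16),
    function() mgayolo:::ghost_bottleneck_block(16, 16),
    function() mgayolo:::mbconv_block(16, 16, 2, "cbam"))
  for (mk in makers) {
    blk <- mk()
    mgayolo:::module_walk(blk, function(l) {
      l$w[] <- 0
      if (!is.null(l$b)) l$b[] <- 0
      if (l$bn) { l$gamma[] <- 0; l$beta[] <- 0 }
    })
    expect_equal(blk_eval(blk, x), x)
  }
})

test_that("standard blocks: focus, SPP and plain conv meet their contracts", {
  x <- rand_fmap(16, 16, 3, 1)
  fc <- mgayolo:::focus_block(3, 8)
  expect_equal(dim(blk_eval(fc, x)), c(8, 8, 8, 1))
  expect_equal(fc$children$conv$c1, 12)  # 2x2 space-to-depth
  xs <- rand_fmap(8, 8, 32, 1)
  sp <- mgayolo:::spp_block(32, 32)
  expect_equal(dim(blk_eval(sp, xs)), c(8, 8, 32, 1))
  expect_equal(sp$children$cv2$c1, 4 * 16)  # pools quadruple pre-projection
  # conv MAC accounting: h' w' k k c n
  cv <- mgayolo:::conv_block(16, 32, 3, 1)
  expect_equal(unname(mgayolo:::blk_profile(cv, c(10, 10))$stats["macs"]),
               10 * 10 * 3 * 3 * 16 * 32)
  expect_error(mgayolo:::ag_concat(list(list(v = rand_fmap(4, 4, 8, 1)),
                                        list(v = rand_fmap(8, 8, 8, 1))),
                                   mgayolo:::ag_ctx()),
               "concat")
})
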