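# Network building blocks.
#
# GhostConv computes half its output channels with an ordinary convolution
# (the "intrinsic" maps) and derives the other half from them with a cheap
# 5x5 depthwise convolution (the "ghost" maps); the two halves are
# concatenated, so roughly half of the multiply-accumulates of a dense
# convolution are saved (ghost ratio s = 2).  GhostBottleneck stacks two
# GhostConvs around a 3x3 depthwise conv with an identity shortcut.  MBConvA
# is an inverted residual bottleneck (1x1 expand -> 3x3 depthwise -> 1x1
# linear projection) whose expanded maps pass through an attention module:
# CBAM by default, with squeeze-excitation and coordinate attention available
# for ablations.  csp_stage() is the two-branch C3 skeleton that hosts any of
# the inner blocks (plain Bottleneck -> C3, GhostBottleneck -> C3Ghost,
# MBConvA -> C3MB).

ghost_conv_block <- function(c1, c2, k = 1, s = 1, act = "silu") {
  if (c2 %% 2 != 0)
    stop("configuration error: GhostConv out_channels must be even, got ", c2)
  cg <- c2 %/% 2
  new_module("ghost_conv", c1 = c1, c2 = c2,
             children = list(
               primary = conv_block(c1, cg, k, s, act = act),
               cheap = conv_block(cg, cg, 5, 1, g = cg, act = act)))
}

#' @export
blk_fwd.yolo_ghost_conv <- function(m, x, ctx) {
  if (dim(x$v)[3] != m$c1)
    stop("shape error: GhostConv expects ", m$c1, " channels, got ",
         dim(x$v)[3])
  y1 <- blk_fwd(m$children$primary, x, ctx)
  y2 <- blk_fwd(m$children$cheap, y1, ctx)
  ag_concat(list(y1, y2), ctx)
}

#' @export
blk_profile.yolo_ghost_conv <- function(m, hw) {
  p1 <- blk_profile(m$children$primary, hw)
  p2 <- blk_profile(m$children$cheap, p1$hw)
  list(hw = p2$hw, stats = p1$stats + p2$stats)
}

ghost_bottleneck_block <- function(c1, c2, act = "silu") {
  if (c1 != c2)
    stop("configuration error: GhostBottleneck shortcut needs in = out channels")
  cg <- c1 %/% 2
  new_module("ghost_bottleneck", c1 = c1, c2 = c2,
             children = list(
               expand = ghost_conv_block(c1, cg, 1, 1, act),
               dw = conv_block(cg, cg, 3, 1, g = cg, act = "none"),
               project = ghost_conv_block(cg, c2, 1, 1, act = "none")))
}

#' @export
blk_fwd.yolo_ghost_bottleneck <- function(m, x, ctx) {
  y <- blk_fwd(m$children$expand, x, ctx)
  y <- blk_fwd(m$children$dw, y, ctx)
  y <- blk_fwd(m$children$project, y, ctx)
  ag_add(x, y, ctx)
}

bottleneck_block <- function(c1, c2, shortcut = TRUE, act = "silu") {
  new_module("bottleneck", c1 = c1, c2 = c2,
             shortcut = shortcut && c1 == c2,
             children = list(cv1 = conv_block(c1, c2, 1, 1, act = act),
                             cv2 = conv_block(c2, c2, 3, 1, act = act)))
}

#' @export
blk_fwd.yolo_bottleneck <- function(m, x, ctx) {
  y <- blk_fwd(m$children$cv2, blk_fwd(m$children$cv1, x, ctx), ctx)
  if (m$shortcut) ag_add(x, y, ctx) else y
}

# ---- attention modules ---------------------------------------------------

se_block <- function(c, reduction = 4) {
  mid <- max(1L, c %/% reduction)
  new_module("se", c1 = c, c2 = c, reduction = reduction,
             children = list(
               fc1 = conv_block(c, mid, 1, act = "relu", bn = FALSE, bias = TRUE),
               fc2 = conv_block(mid, c, 1, act = "none", bn = FALSE, bias = TRUE)))
}

#' @export
blk_fwd.yolo_se <- function(m, x, ctx) {
  s <- ag_gap(x, ctx)
  s <- blk_fwd(m$children$fc2, blk_fwd(m$children$fc1, s, ctx), ctx)
  ag_mul_bc(x, ag_act(s, "sigmoid", ctx), ctx)
}

cbam_block <- function(c, reduction = 16, spatial_kernel = 3) {
  if (c < reduction)
    stop("configuration error: CBAM needs at least 'reduction' channels")
  mid <- max(1L, c %/% reduction)
  new_module("cbam", c1 = c, c2 = c, reduction = reduction,
             spatial_kernel = spatial_kernel,
             children = list(
               fc1 = conv_block(c, mid, 1, act = "relu", bn = FALSE, bias = TRUE),
               fc2 = conv_block(mid, c, 1, act = "none", bn = FALSE, bias = TRUE),
               spatial = conv_block(2, 1, spatial_kernel, act = "none",
                                    bn = FALSE, bias = TRUE)))
}

#' @export
blk_fwd.yolo_cbam <- function(m, x, ctx) {
  mlp <- function(s) blk_fwd(m$children$fc2, blk_fwd(m$children$fc1, s, ctx), ctx)
  catt <- ag_act(ag_add(mlp(ag_gap(x, ctx)), mlp(ag_gmp(x, ctx)), ctx),
                 "sigmoid", ctx)
  x1 <- ag_mul_bc(x, catt, ctx)
  satt <- ag_act(blk_fwd(m$children$spatial, ag_chpool(x1, ctx), ctx),
                 "sigmoid", ctx)
  ag_mul_bc(x1, satt, ctx)
}

ca_block <- function(c, reduction = 32) {
  mip <- max(8L, c %/% reduction)
  new_module("ca", c1 = c, c2 = c, reduction = reduction, mip = mip,
             children = list(
               squeeze = conv_block(c, mip, 1, act = "hswish", bn = TRUE,
                                    bias = TRUE),
               conv_h = conv_block(mip, c, 1, act = "none", bn = FALSE,
                                   bias = TRUE),
               conv_w = conv_block(mip, c, 1, act = "none", bn = FALSE,
                                   bias = TRUE)))
}

#' @export
blk_fwd.yolo_ca <- function(m, x, ctx) {
  d <- dim(x$v)
  xh <- ag_pool_w(x, ctx)              # (H, 1, C, N)
  xw <- ag_pool_h(x, ctx)              # (W, 1, C, N)
  strip <- blk_fwd(m$children$squeeze, ag_cat_rows(list(xh, xw), ctx), ctx)
  sh <- ag_slice_rows(strip, seq_len(d[1]), ctx)
  sw <- ag_slice_rows(strip, d[1] + seq_len(d[2]), ctx)
  ah <- ag_act(blk_fwd(m$children$conv_h, sh, ctx), "sigmoid", ctx)
  aw <- ag_act(blk_fwd(m$children$conv_w, sw, ctx), "sigmoid", ctx)
  ag_mul_bc(ag_mul_bc(x, ah, ctx), ag_transpose_strip(aw, ctx), ctx)
}

attention_block <- function(kind, c) {
  switch(kind,
    none = NULL,
    se = se_block(c),
    cbam = cbam_block(c),
    ca = ca_block(c),
    stop("configuration error: unknown attention kind '", kind, "'"))
}

# ---- inverted residual bottleneck with attention -------------------------

mbconv_block <- function(c1, c2, expansion = 6, attention = "cbam",
                         act = "silu") {
  if (expansion < 1) stop("configuration error: expansion must be >= 1")
  h <- as.integer(round(c1 * expansion))
  children <- list(
    expand = conv_block(c1, h, 1, act = act),
    dw = conv_block(h, h, 3, 1, g = h, act = "none"))
  att <- attention_block(attention, h)
  if (!is.null(att)) children$attention <- att
  children$project <- conv_block(h, c2, 1, act = "none")
  new_module("mbconv", c1 = c1, c2 = c2, expansion = expansion,
             attention = attention, hidden = h,
             shortcut = c1 == c2, children = children)
}

#' @export
blk_fwd.yolo_mbconv <- function(m, x, ctx) {
  y <- blk_fwd(m$children$dw, blk_fwd(m$children$expand, x, ctx), ctx)
  if (!is.null(m$children$attention))
    y <- blk_fwd(m$children$attention, y, ctx)
  y <- blk_fwd(m$children$project, y, ctx)
  if (m$shortcut) ag_add(x, y, ctx) else y
}

# ---- CSP stage (C3 / C3Ghost / C3MB) -------------------------------------

csp_stage <- function(c1, c2, n = 1, inner = "bottleneck", shortcut = TRUE,
                      act = "silu", attention = "none", expansion = 6) {
  if (n < 1) stop("configuration error: repeats must be >= 1")
  cg <- c2 %/% 2
  make_inner <- function() {
    switch(inner,
      bottleneck = bottleneck_block(cg, cg, shortcut, act),
      ghost_bottleneck = ghost_bottleneck_block(cg, cg, act),
      mbconv_a = mbconv_block(cg, cg, expansion, attention, act),
      stop("configuration error: unknown inner block '", inner, "'"))
  }
  inners <- lapply(seq_len(n), function(i) make_inner())
  names(inners) <- paste0("m", seq_len(n))
  new_module("csp", c1 = c1, c2 = c2, n = n, inner = inner,
             children = c(list(cv1 = conv_block(c1, cg, 1, act = act),
                               cv2 = conv_block(c1, cg, 1, act = act),
                               cv3 = conv_block(2 * cg, c2, 1, act = act)),
                          inners))
}

#' @export
blk_fwd.yolo_csp <- function(m, x, ctx) {
  a <- blk_fwd(m$children$cv1, x, ctx)
  for (i in seq_len(m$n)) a <- blk_fwd(m$children[[paste0("m", i)]], a, ctx)
  b <- blk_fwd(m$children$cv2, x, ctx)
  blk_fwd(m$children$cv3, ag_concat(list(a, b), ctx), ctx)
}

# ---- stem, pyramid pooling, plumbing -------------------------------------

focus_block <- function(c1, c2, k = 3, act = "silu") {
  new_module("focus", c1 = c1, c2 = c2,
             children = list(conv = conv_block(4 * c1, c2, k, act = act)))
}

#' @export
blk_fwd.yolo_focus <- function(m, x, ctx)
  blk_fwd(m$children$conv, ag_focus_slice(x, ctx), ctx)

#' @export
blk_profile.yolo_focus <- function(m, hw)
  blk_profile(m$children$conv, hw %/% 2L)

spp_block <- function(c1, c2, ks = c(5, 9, 13), act = "silu") {
  ch <- c1 %/% 2
  new_module("spp", c1 = c1, c2 = c2, ks = ks,
             children = list(cv1 = conv_block(c1, ch, 1, act = act),
                             cv2 = conv_block(ch * (length(ks) + 1), c2, 1,
                                              act = act)))
}

#' @export
blk_fwd.yolo_spp <- function(m, x, ctx) {
  y <- blk_fwd(m$children$cv1, x, ctx)
  pools <- lapply(m$ks, function(k) ag_maxpool(y, k, ctx))
  blk_fwd(m$children$cv2, ag_concat(c(list(y), pools), ctx), ctx)
}

upsample_block <- function(c1) new_module("upsample", c1 = c1, c2 = c1)

#' @export
blk_fwd.yolo_upsample <- function(m, x, ctx) ag_upsample2(x, ctx)

concat_block <- function(c_in) new_module("concat", c1 = sum(c_in), c2 = sum(c_in))

#' @export
blk_fwd.yolo_concat <- function(m, x, ctx) ag_concat(x, ctx)

detect_block <- function(nc, anchors, ch) {
  na <- length(anchors[[1]]) / 2
  no <- nc + 5
  convs <- lapply(ch, function(c)
    conv_block(c, na * no, 1, act = "none", bn = FALSE, bias = TRUE))
  names(convs) <- paste0("head", seq_along(convs))
  new_module("detect", c1 = ch, c2 = na * no, nc = nc, na = na, no = no,
             anchors = anchors, children = convs)
}

#' @export
blk_fwd.yolo_detect <- function(m, x, ctx)
  lapply(seq_along(x), function(i) blk_fwd(m$children[[i]], x[[i]], ctx))

# ---- profile methods for composite blocks --------------------------------

profile_children <- function(children, hw) {
  stats <- c(params = 0, macs = 0, bn_elems = 0, pool_elems = 0)
  for (ch in children) {
    p <- blk_profile(ch, hw)
    hw <- p$hw
    stats <- stats + p$stats
  }
  list(hw = hw, stats = stats)
}

#' @export
blk_profile.yolo_ghost_bottleneck <- function(m, hw)
  profile_children(m$children, hw)

#' @export
blk_profile.yolo_bottleneck <- function(m, hw) profile_children(m$children, hw)

#' @export
blk_profile.yolo_se <- function(m, hw) {
  p1 <- blk_profile(m$children$fc1, c(1, 1))
  p2 <- blk_profile(m$children$fc2, c(1, 1))
  st <- p1$stats + p2$stats
  st["pool_elems"] <- m$c1 * hw[1] * hw[2]  # global average pool reads x once
  list(hw = hw, stats = st)
}

#' @export
blk_profile.yolo_cbam <- function(m, hw) {
  p1 <- blk_profile(m$children$fc1, c(1, 1))
  p2 <- blk_profile(m$children$fc2, c(1, 1))
  ps <- blk_profile(m$children$spatial, hw)
  st <- p1$stats + p2$stats + ps$stats
  st["macs"] <- st["macs"] + p1$stats["macs"] + p2$stats["macs"]  # MLP runs twice
  st["pool_elems"] <- m$c1 * hw[1] * hw[2]  # avg pool; max pools count zero
  list(hw = hw, stats = st)
}

#' @export
blk_profile.yolo_ca <- function(m, hw) {
  strip <- c(hw[1] + hw[2], 1)
  psq <- blk_profile(m$children$squeeze, strip)
  ph <- blk_profile(m$children$conv_h, c(hw[1], 1))
  pw <- blk_profile(m$children$conv_w, c(hw[2], 1))
  st <- psq$stats + ph$stats + pw$stats
  st["pool_elems"] <- 2 * m$c1 * hw[1] * hw[2]  # two directional average pools
  list(hw = hw, stats = st)
}

#' @export
blk_profile.yolo_mbconv <- function(m, hw) profile_children(m$children, hw)

#' @export
blk_profile.yolo_csp <- function(m, hw) {
  st <- blk_profile(m$children$cv1, hw)$stats +
    blk_profile(m$children$cv2, hw)$stats +
    blk_profile(m$children$cv3, hw)$stats
  for (i in seq_len(m$n))
    st <- st + blk_profile(m$children[[paste0("m", i)]], hw)$stats
  list(hw = hw, stats = st)
}

#' @export
blk_profile.yolo_spp <- function(m, hw) {
  st <- blk_profile(m$children$cv1, hw)$stats +
    blk_profile(m$children$cv2, hw)$stats
  list(hw = hw, stats = st)  # max pools contribute no counted ops
}

#' @export
blk_profile.yolo_upsample <- function(m, hw)
  list(hw = hw * 2L, stats = c(params = 0, macs = 0, bn_elems = 0,
                               pool_elems = 0))

#' @export
blk_profile.yolo_concat <- function(m, hw)
  list(hw = hw, stats = c(params = 0, macs = 0, bn_elems = 0, pool_elems = 0))

#' @export
blk_profile.yolo_detect <- function(m, hw_list) {
  st <- c(params = 0, macs = 0, bn_elems = 0, pool_elems = 0)
  for (i in seq_along(m$children))
    st <- st + blk_profile(m$children[[i]], hw_list[[i]])$stats
  list(hw = hw_list, stats = st)
}
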