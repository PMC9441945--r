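#' Build a detection model from a declarative configuration
#'
#' A configuration describes the layer graph the same way the YOLO family's
#' YAML files do: an ordered list of layers, each with the index (or indices)
#' of its input layers, a repeat count, a block kind and block arguments.
#' Channel widths are multiplied by `width_multiple` and rounded up to a
#' multiple of 8; CSP-stage repeat counts are multiplied by `depth_multiple`
#' with a minimum of 1.  Use [mga_config()] for the bundled configurations
#' covering the whole ablation ladder from the YOLOv5s baseline to MGA-YOLO.
#'
#' @param cfg a model configuration list (see [mga_config()] /
#'   [read_model_config()]).
#' @return an object of class `mga_model`: the built layer graph plus derived
#'   metadata (`strides`, `head_channels`, the configuration).
#' @examples
#' m <- build_model(mga_config("yolov5s", width_multiple = 0.25))
#' count_parameters(m)
#' @export
build_model <- function(cfg) {
  cfg <- validate_config(cfg)
  wm <- cfg$width_multiple
  dm <- cfg$depth_multiple
  act <- cfg$activation
  specs <- c(cfg$backbone, cfg$head)
  nl <- length(specs)
  layers <- vector("list", nl)
  ch <- integer(nl)
  detect_idx <- NA_integer_
  for (i in seq_len(nl)) {
    sp <- specs[[i]]
    from <- sp$from
    from_abs <- ifelse(from == -1, i - 1L, as.integer(from))
    if (any(from_abs >= i) || any(from_abs < 1 & sp$kind != "focus"))
      stop("configuration error: layer ", i, " references layer(s) ",
           paste(from_abs, collapse = ","), " not yet built")
    c1 <- if (i == 1) 3L else ch[from_abs[1]]
    n <- max(1L, sp$repeats)
    args <- sp$args
    scale_ch <- function(c) {
      c_sc <- make_divisible(c * wm, 8)
      c_sc
    }
    m <- switch(sp$kind,
      focus = {
        c2 <- scale_ch(args[[1]])
        focus_block(3, c2, if (length(args) > 1) args[[2]] else 3, act)
      },
      conv = {
        c2 <- scale_ch(args[[1]])
        conv_block(c1, c2, args[[2]], args[[3]], act = act)
      },
      ghost_conv = {
        c2 <- scale_ch(args[[1]])
        ghost_conv_block(c1, c2, args[[2]], args[[3]], act)
      },
      c3 = {
        c2 <- scale_ch(args[[1]])
        csp_stage(c1, c2, scale_depth(n, dm),
                  "bottleneck", isTRUE(args[[2]]) || length(args) < 2, act)
      },
      c3ghost = {
        c2 <- scale_ch(args[[1]])
        csp_stage(c1, c2, scale_depth(n, dm),
                  "ghost_bottleneck", TRUE, act)
      },
      c3mb = {
        c2 <- scale_ch(args[[1]])
        csp_stage(c1, c2, scale_depth(n, dm), "mbconv_a", TRUE, act,
                  attention = if (length(args) > 2) args[[3]] else "none",
                  expansion = if (length(args) > 3) args[[4]] else 6)
      },
      spp = {
        c2 <- scale_ch(args[[1]])
        spp_block(c1, c2, if (length(args) > 1) args[[2]] else c(5, 9, 13), act)
      },
      upsample = upsample_block(c1),
      concat = concat_block(ch[from_abs]),
      detect = detect_block(cfg$nc, cfg$anchors, ch[from_abs]),
      stop("configuration error: unknown block kind '", sp$kind, "'")
    )
    m$from <- from_abs
    m$kind <- sp$kind
    ch[i] <- if (sp$kind == "detect") 0L else m$c2
    if (sp$kind == "detect") detect_idx <- i
    layers[[i]] <- m
  }
  if (is.na(detect_idx))
    stop("configuration error: configuration has no detect layer")
  model <- new.env(parent = emptyenv())
  model$cfg <- cfg
  model$layers <- layers
  model$ch <- ch
  model$nc <- cfg$nc
  model$detect_idx <- detect_idx
  model$head_channels <- 3L * (cfg$nc + 5L)
  class(model) <- "mga_model"
  shapes <- layer_shapes(model, 256L)
  hw_heads <- shapes[layers[[detect_idx]]$from]
  model$strides <- vapply(hw_heads, function(h) as.integer(256 %/% h[1]),
                          integer(1))
  det <- layers[[detect_idx]]
  if (length(cfg$anchors) != length(det$from))
    stop("configuration error: ", length(cfg$anchors),
         " anchor sets for ", length(det$from), " detection layers")
  init_detect_biases(det, model$strides, cfg$nc)
  model
}

scale_depth <- function(n, dm) max(1L, as.integer(round(n * dm)))

# prior initialisation of the detection biases: objectness starts at roughly
# 8 objects per 640x640 image at each scale and every class at ~0.6/nc, so
# early training is not dominated by suppressing background confidence
init_detect_biases <- function(det, strides, nc) {
  no <- nc + 5L
  for (i in seq_along(det$children)) {
    l <- det$children[[i]]
    b <- l$b
    for (a in seq_len(det$na)) {
      b[(a - 1) * no + 5] <- log(8 / (640 / strides[i])^2)
      b[(a - 1) * no + 5 + seq_len(nc)] <- log(0.6 / (nc - 0.99))
    }
    l$b <- b
  }
  invisible(det)
}

make_divisible <- function(x, d) {
  r <- as.integer(ceiling(x / d) * d)
  if (abs(r - x) > 1e-9 && x > d)
    warning("channel width ", x, " rounded to multiple of 8: ", r)
  r
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$nc), !is.null(cfg$backbone),
            !is.null(cfg$head))
  if (is.null(cfg$depth_multiple)) cfg$depth_multiple <- 1
  if (is.null(cfg$width_multiple)) cfg$width_multiple <- 1
  if (is.null(cfg$activation)) cfg$activation <- "silu"
  if (is.null(cfg$anchors)) stop("configuration error: anchors missing")
  cfg
}

# spatial size (square input) after every layer; used for strides and FLOPs
layer_shapes <- function(model, img_size) {
  nl <- length(model$layers)
  shp <- vector("list", nl)
  for (i in seq_len(nl)) {
    m <- model$layers[[i]]
    hw_in <- if (i == 1) c(img_size, img_size) else shp[[m$from[1]]]
    shp[[i]] <- switch(m$kind,
      detect = hw_in,
      upsample = hw_in * 2L,
      blk_profile(m, hw_in)$hw)
  }
  shp
}

#' Run a model forward
#'
#' Applies the network to a batch of RGB images and returns the raw
#' prediction map of every detection head (channels
#' `3 * (nc + 5)` at input resolution divided by the head stride).
#' Outputs are deterministic in evaluation mode.
#'
#' @param model an `mga_model`.
#' @param x numeric array `(H, W, 3)` or `(H, W, 3, N)` with values in
#'   \[0, 1\].
#' @param training logical; use batch statistics and record gradients.
#' @param ctx internal autodiff context; supply only from [fit_model()].
#' @return list with one raw prediction array per head (training = FALSE), or
#'   the corresponding tape nodes (training = TRUE).
#' @export
model_forward <- function(model, x, training = FALSE, ctx = NULL) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  smax <- max(model$strides)
  if (any(dim(x)[1:2] %% smax != 0))
    stop("shape error: input size ", dim(x)[1], "x", dim(x)[2],
         " must be a multiple of ", smax)
  own_ctx <- is.null(ctx)
  if (own_ctx) ctx <- ag_ctx(training = training)
  out <- model_forward_nodes(model, ag_input(x, ctx), ctx)
  if (own_ctx && !ctx$rec) lapply(out, function(nd) nd$v) else out
}

model_forward_nodes <- function(model, xnode, ctx) {
  nl <- length(model$layers)
  outs <- vector("list", nl)
  for (i in seq_len(nl)) {
    m <- model$layers[[i]]
    xin <- if (i == 1) xnode
      else if (length(m$from) == 1) outs[[m$from]]
      else lapply(m$from, function(j) outs[[j]])
    outs[[i]] <- blk_fwd(m, xin, ctx)
  }
  outs[[model$detect_idx]]
}

#' Count trainable parameters
#'
#' Sums the element counts of every trainable array in the model: convolution
#' weights, biases where present, and batch-norm scale/shift pairs.
#'
#' @param model an `mga_model` or any single block environment.
#' @return integer-valued total.
#' @export
count_parameters <- function(model) {
  total <- 0
  walk1 <- function(m) {
    module_walk(m, function(l) {
      total <<- total + length(l$w) + length(l$b) +
        (if (l$bn) 2 * l$c2 else 0)
    })
  }
  if (inherits(model, "mga_model")) {
    for (m in model$layers) walk1(m)
  } else {
    walk1(model)
  }
  total
}

#' Profile parameters and FLOPs
#'
#' Computes per-layer parameter counts and multiply-accumulate counts for a
#' square input, following the profiling convention of common detection
#' tooling: convolutions contribute \eqn{k^2 c_{in} c_{out} H W / g} MACs,
#' batch-norm layers 2 ops per output element, average-pooling reductions one
#' op per input element, and plain max-pooling, upsampling, concatenation and
#' activations nothing.  Reported GFLOPs are `2 * total / 1e9`.
#'
#' @param model an `mga_model`.
#' @param img_size input edge length in pixels (must be divisible by the
#'   largest stride).
#' @return an object of class `mga_profile` with `total_params`, `gmacs`,
#'   `gflops` and a `per_layer` data frame.
#' @examples
#' estimate_flops(build_model(mga_config("yolov5s", width_multiple = 0.25)), 256)
#' @export
estimate_flops <- function(model, img_size = 640) {
  smax <- max(model$strides)
  if (img_size %% smax != 0)
    stop("shape error: img_size must be a multiple of ", smax)
  nl <- length(model$layers)
  shp <- vector("list", nl)
  rows <- vector("list", nl)
  for (i in seq_len(nl)) {
    m <- model$layers[[i]]
    hw_in <- if (i == 1) c(img_size, img_size) else shp[[m$from[1]]]
    if (m$kind == "detect") {
      p <- blk_profile(m, lapply(m$from, function(j) shp[[j]]))
      shp[[i]] <- hw_in
    } else {
      p <- blk_profile(m, hw_in)
      shp[[i]] <- p$hw
    }
    rows[[i]] <- data.frame(layer = i, kind = m$kind,
                            params = unname(p$stats["params"]),
                            conv_macs = unname(p$stats["macs"]),
                            pointwise_ops = unname(2 * p$stats["bn_elems"] +
                                                     p$stats["pool_elems"]))
  }
  per_layer <- do.call(rbind, rows)
  total_ops <- sum(per_layer$conv_macs) + sum(per_layer$pointwise_ops)
  out <- list(total_params = sum(per_layer$params),
              gmacs = total_ops / 1e9,
              gflops = 2 * total_ops / 1e9,
              img_size = img_size,
              per_layer = per_layer)
  class(out) <- "mga_profile"
  out
}

#' @export
print.mga_profile <- function(x, ...) {
  cat(sprintf("Model profile at %dx%d\n", x$img_size, x$img_size))
  cat(sprintf("  parameters : %s\n", format(x$total_params, big.mark = ",")))
  cat(sprintf("  GMACs      : %.2f\n", x$gmacs))
  cat(sprintf("  GFLOPs     : %.1f\n", x$gflops))
  invisible(x)
}

#' Decode raw head maps into detections
#'
#' Applies the anchor-based decoding of the YOLO head: sigmoid centre offsets
#' scaled to \[-0.5, 1.5\] around each cell, squared sigmoid width/height
#' scaled by the anchor, objectness times best class probability as
#' confidence.  Boxes are clipped to the image and returned in pixel
#' xyxy coordinates.
#'
#' @param preds list of raw head arrays from [model_forward()].
#' @param model the `mga_model` that produced them.
#' @param conf_thr confidence threshold; only detections with
#'   `confidence > conf_thr` are returned.
#' @return data frame with columns `image`, `class_id` (0-based),
#'   `confidence`, `x1`, `y1`, `x2`, `y2`.
#' @export
decode_predictions <- function(preds, model, conf_thr = 0.25) {
  if (length(preds) != length(model$strides))
    stop("configuration error: ", length(preds), " head maps for ",
         length(model$strides), " strides")
  nc <- model$nc
  no <- nc + 5L
  res <- list()
  for (h in seq_along(preds)) {
    p <- preds[[h]]
    d <- dim(p)
    stride <- model$strides[h]
    na <- d[3] %/% no
    anc <- matrix(model$cfg$anchors[[h]], nrow = 2)
    img_h <- d[1] * stride
    img_w <- d[2] * stride
    gy <- rep(seq_len(d[1]) - 1L, times = d[2])
    gx <- rep(seq_len(d[2]) - 1L, each = d[1])
    for (n in seq_len(d[4])) for (a in seq_len(na)) {
      sl <- matrix(p[, , (a - 1) * no + seq_len(no), n], d[1] * d[2], no)
      obj <- stats::plogis(sl[, 5])
      cls <- stats::plogis(sl[, 5 + seq_len(nc), drop = FALSE])
      best <- max.col(cls, ties.method = "first")
      conf <- obj * cls[cbind(seq_along(best), best)]
      keep <- which(conf > conf_thr)
      if (length(keep) == 0) next
      bx <- (2 * stats::plogis(sl[keep, 1]) - 0.5 + gx[keep]) * stride
      by <- (2 * stats::plogis(sl[keep, 2]) - 0.5 + gy[keep]) * stride
      bw <- (2 * stats::plogis(sl[keep, 3]))^2 * anc[1, a]
      bh <- (2 * stats::plogis(sl[keep, 4]))^2 * anc[2, a]
      df <- data.frame(
        image = n, class_id = best[keep] - 1L, confidence = conf[keep],
        x1 = pmin(pmax(bx - bw / 2, 0), img_w),
        y1 = pmin(pmax(by - bh / 2, 0), img_h),
        x2 = pmin(pmax(bx + bw / 2, 0), img_w),
        y2 = pmin(pmax(by + bh / 2, 0), img_h))
      # clipping can collapse boxes that lay mostly outside the image
      df <- df[df$x2 - df$x1 >= 1 & df$y2 - df$y1 >= 1, , drop = FALSE]
      if (nrow(df) > 0) res[[length(res) + 1]] <- df
    }
  }
  if (length(res) == 0)
    return(data.frame(image = integer(), class_id = integer(),
                      confidence = numeric(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  out <- do.call(rbind, res)
  out[order(-out$confidence), , drop = FALSE]
}

#' @export
print.mga_model <- function(x, ...) {
  cat(sprintf("<mga_model> %s  nc=%d  heads=%d  strides=%s  params=%s\n",
              x$cfg$name %||% "custom", x$nc, length(x$strides),
              paste(x$strides, collapse = "/"),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
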