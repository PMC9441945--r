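# Primitive layer: convolution with optional batch-norm and activation.
# Every learnable block in the package bottoms out in these environments, so
# parameter counting, gradient zeroing and SGD updates are implemented as a
# single recursive walk over them.

new_module <- function(type, children = list(), ...) {
  m <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  m$children <- children
  class(m) <- c(paste0("yolo_", type), "yolo_module")
  m
}

conv_block <- function(c1, c2, k = 1, s = 1, g = 1, act = "silu", bn = TRUE,
                       bias = FALSE) {
  if (k %% 2 != 1) stop("configuration error: kernel size must be odd")
  if (c1 %% g != 0 || c2 %% g != 0)
    stop("configuration error: channels not divisible by groups")
  m <- new_module("conv", c1 = c1, c2 = c2, k = k, stride = s, pad = (k - 1) %/% 2,
                  groups = g, act = act, bn = bn)
  fan_in <- k * k * c1 / g
  m$w <- array(stats::rnorm(k * k * (c1 / g) * c2, sd = sqrt(2 / fan_in)),
               c(k, k, c1 / g, c2))
  m$b <- if (bias) numeric(c2) else NULL
  if (bn) {
    m$gamma <- rep(1, c2)
    m$beta <- numeric(c2)
    m$rmean <- numeric(c2)
    m$rvar <- rep(1, c2)
    m$eps <- 1e-3
    m$mom <- 0.03
  }
  zero_grads(m)
  m
}

# visit every primitive conv layer below m
module_walk <- function(m, fn) {
  if (inherits(m, "yolo_conv")) {
    fn(m)
  } else {
    for (ch in m$children) module_walk(ch, fn)
  }
  invisible(NULL)
}

zero_grads <- function(m) {
  module_walk(m, function(l) {
    l$gw <- array(0, dim(l$w))
    if (!is.null(l$b)) l$gb <- numeric(l$c2)
    if (l$bn) {
      l$ggamma <- numeric(l$c2)
      l$gbeta <- numeric(l$c2)
    }
  })
}

# flat named list of parameter arrays (brute-force enumeration surface)
module_params <- function(m, prefix = "") {
  out <- list()
  if (inherits(m, "yolo_conv")) {
    out[[paste0(prefix, "w")]] <- m$w
    if (!is.null(m$b)) out[[paste0(prefix, "b")]] <- m$b
    if (m$bn) {
      out[[paste0(prefix, "gamma")]] <- m$gamma
      out[[paste0(prefix, "beta")]] <- m$beta
    }
  } else {
    nms <- names(m$children)
    if (is.null(nms)) nms <- as.character(seq_along(m$children))
    for (i in seq_along(m$children))
      out <- c(out, module_params(m$children[[i]],
                                  paste0(prefix, nms[i], ".")))
  }
  out
}

# SGD with momentum; weight decay applies to conv weights only (the usual
# YOLO convention: BN affine terms and biases are decay-free).  Biases and
# BN shifts may use their own learning rate (larger during warmup).
sgd_step <- function(m, lr, momentum = 0.937, weight_decay = 0,
                     lr_bias = lr) {
  module_walk(m, function(l) {
    if (is.null(l$vw)) {
      l$vw <- array(0, dim(l$w))
      if (!is.null(l$b)) l$vb <- numeric(l$c2)
      if (l$bn) {
        l$vgamma <- numeric(l$c2)
        l$vbeta <- numeric(l$c2)
      }
    }
    l$vw <- momentum * l$vw + l$gw + weight_decay * l$w
    l$w <- l$w - lr * l$vw
    if (!is.null(l$b)) {
      l$vb <- momentum * l$vb + l$gb
      l$b <- l$b - lr_bias * l$vb
    }
    if (l$bn) {
      l$vgamma <- momentum * l$vgamma + l$ggamma
      l$gamma <- l$gamma - lr * l$vgamma
      l$vbeta <- momentum * l$vbeta + l$gbeta
      l$beta <- l$beta - lr_bias * l$vbeta
    }
  })
}

# ---- generic forward / profile dispatch ----------------------------------

blk_fwd <- function(m, x, ctx) UseMethod("blk_fwd")

#' @export
blk_fwd.yolo_conv <- function(m, x, ctx) ag_conv(x, m, ctx)

# blk_profile returns list(hw = output c(h, w), stats = c(params, macs,
# bn_elems, pool_elems)); channels are static module metadata
blk_profile <- function(m, hw) UseMethod("blk_profile")

#' @export
blk_profile.yolo_conv <- function(m, hw) {
  ho <- (hw[1] + 2 * m$pad - m$k) %/% m$stride + 1
  wo <- (hw[2] + 2 * m$pad - m$k) %/% m$stride + 1
  params <- m$k^2 * (m$c1 / m$groups) * m$c2 +
    (if (!is.null(m$b)) m$c2 else 0) + (if (m$bn) 2 * m$c2 else 0)
  macs <- m$k^2 * (m$c1 / m$groups) * m$c2 * ho * wo
  list(hw = c(ho, wo),
       stats = c(params = params, macs = macs,
                 bn_elems = if (m$bn) m$c2 * ho * wo else 0, pool_elems = 0))
}
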