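# Minimal reverse-mode tape over (H, W, C, N) feature-map arrays.
#
# A "node" wraps a numeric array in $v.  While a context is recording
# (ctx$rec), each op appends an environment carrying a backward closure to
# ctx$tape; running the tape in reverse accumulates gradients into upstream
# nodes and into the parameter fields of the layer environments.  With
# recording off the same code path degenerates to plain array arithmetic, so
# inference and training share one implementation.

ag_ctx <- function(training = FALSE, record = training) {
  ctx <- new.env(parent = emptyenv())
  ctx$training <- training
  ctx$rec <- record
  ctx$tape <- list()
  ctx
}

ag_input <- function(v, ctx) {
  if (ctx$rec) {
    nd <- new.env(parent = emptyenv())
    nd$v <- v
    nd
  } else {
    list(v = v)
  }
}

ag_node <- function(v, ctx, bw = NULL) {
  if (!ctx$rec) return(list(v = v))
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$bw <- bw
  ctx$tape[[length(ctx$tape) + 1L]] <- nd
  nd
}

ag_acc <- function(node, g) {
  if (is.environment(node))
    node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# run the tape in reverse; head gradients must already be assigned
ag_backward <- function(ctx) {
  for (i in rev(seq_along(ctx$tape))) {
    nd <- ctx$tape[[i]]
    if (!is.null(nd$bw) && !is.null(nd$grad)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

# ---- fused conv + batch-norm + activation --------------------------------

act_code <- function(kind) {
  switch(kind, none = 0L, silu = 1L, swish1 = 1L, gelu = 2L,
         leaky_relu = 3L, relu = 4L, hswish = 5L, sigmoid = 6L,
         stop("unknown activation '", kind, "'"))
}

ag_conv <- function(x, m, ctx) {
  z0 <- conv2d_fw(x$v, m$w, m$stride, m$pad, m$groups)
  if (!is.null(m$b)) z0 <- ch_scale_shift(z0, rep(1, m$c2), m$b)
  d <- dim(z0)
  if (m$bn) {
    if (ctx$training) {
      cnt <- d[1] * d[2] * d[4]
      red <- ch_reduce(z0, NULL)
      mu <- red$s1 / cnt
      va <- pmax(red$s2 / cnt - mu^2, 0)
      ivar <- 1 / sqrt(va + m$eps)
      m$rmean <- (1 - m$mom) * m$rmean + m$mom * mu
      ub <- if (cnt > 1) cnt / (cnt - 1) else 1
      m$rvar <- (1 - m$mom) * m$rvar + m$mom * va * ub
    } else {
      mu <- m$rmean
      ivar <- 1 / sqrt(m$rvar + m$eps)
    }
    # single-pass affine: z1 = gamma * (z0 - mu) * ivar + beta
    z1 <- ch_scale_shift(z0, m$gamma * ivar, m$beta - m$gamma * mu * ivar)
  } else {
    z1 <- z0
  }
  code <- act_code(m$act)
  out <- if (code == 0L) z1 else act_fw(z1, code)
  if (!ctx$rec) return(list(v = out))
  training <- ctx$training
  ag_node(out, ctx, bw = function(g) {
    g1 <- if (code == 0L) g else act_bw(z1, g, code)
    if (m$bn) {
      res <- bn_bwd(g1, z0, mu, ivar, m$gamma, training)
      m$ggamma <- m$ggamma + res$s2
      m$gbeta <- m$gbeta + res$s1
      gz0 <- res$gz0
    } else {
      gz0 <- g1
    }
    if (!is.null(m$b)) m$gb <- m$gb + ch_reduce(gz0, NULL)$s1
    bwres <- conv2d_bw(x$v, m$w, gz0, m$stride, m$pad, m$groups)
    m$gw <- m$gw + bwres$gw
    ag_acc(x, bwres$gx)
  })
}

# ---- structural ops ------------------------------------------------------

ag_concat <- function(xs, ctx) {
  ds <- lapply(xs, function(x) dim(x$v))
  cc <- vapply(ds, `[`, 0, 3L)
  d1 <- ds[[1]]
  if (!all(vapply(ds, function(d) all(d[c(1, 2, 4)] == d1[c(1, 2, 4)]), TRUE)))
    stop("concat: spatial or batch dimensions disagree")
  out <- array(0, c(d1[1], d1[2], sum(cc), d1[4]))
  off <- 0L
  for (i in seq_along(xs)) {
    out[, , off + seq_len(cc[i]), ] <- xs[[i]]$v
    off <- off + cc[i]
  }
  if (!ctx$rec) return(list(v = out))
  ag_node(out, ctx, bw = function(g) {
    off <- 0L
    for (i in seq_along(xs)) {
      ag_acc(xs[[i]], g[, , off + seq_len(cc[i]), , drop = FALSE])
      off <- off + cc[i]
    }
  })
}

ag_add <- function(a, b, ctx) {
  out <- a$v + b$v
  if (!ctx$rec) return(list(v = out))
  ag_node(out, ctx, bw = function(g) {
    ag_acc(a, g)
    ag_acc(b, g)
  })
}

ag_upsample2 <- function(x, ctx) {
  d <- dim(x$v)
  out <- x$v[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
             drop = FALSE]
  if (!ctx$rec) return(list(v = out))
  ag_node(out, ctx, bw = function(g) {
    oh <- seq(1, 2 * d[1], by = 2)
    ow <- seq(1, 2 * d[2], by = 2)
    gx <- g[oh, ow, , , drop = FALSE] + g[oh + 1, ow, , , drop = FALSE] +
      g[oh, ow + 1, , , drop = FALSE] + g[oh + 1, ow + 1, , , drop = FALSE]
    ag_acc(x, gx)
  })
}

ag_maxpool <- function(x, k, ctx) {
  res <- maxpool_fw(x$v, as.integer(k), 1L, as.integer((k - 1) / 2))
  if (!ctx$rec) return(list(v = res$y))
  d <- dim(x$v)
  ag_node(res$y, ctx, bw = function(g) {
    ag_acc(x, maxpool_bw(res$idx, g, as.integer(d)))
  })
}

# space-to-depth 2x2 slicing used by the Focus stem
ag_focus_slice <- function(x, ctx) {
  d <- dim(x$v)
  oh <- seq(1, d[1], by = 2)
  ow <- seq(1, d[2], by = 2)
  parts <- list(x$v[oh, ow, , , drop = FALSE], x$v[oh + 1, ow, , , drop = FALSE],
                x$v[oh, ow + 1, , , drop = FALSE],
                x$v[oh + 1, ow + 1, , , drop = FALSE])
  out <- array(0, c(d[1] / 2, d[2] / 2, 4 * d[3], d[4]))
  for (i in 1:4) out[, , (i - 1) * d[3] + seq_len(d[3]), ] <- parts[[i]]
  if (!ctx$rec) return(list(v = out))
  ag_node(out, ctx, bw = function(g) {
    gx <- array(0, d)
    sel <- list(list(oh, ow), list(oh + 1, ow), list(oh, ow + 1),
                list(oh + 1, ow + 1))
    for (i in 1:4)
      gx[sel[[i]][[1]], sel[[i]][[2]], , ] <-
        g[, , (i - 1) * d[3] + seq_len(d[3]), , drop = FALSE]
    ag_acc(x, gx)
  })
}

# ---- pooling / reweighting ops used by attention blocks ------------------

ag_gap <- function(x, ctx) {
  d <- dim(x$v)
  mu <- .colMeans(x$v, d[1] * d[2], d[3] * d[4])
  out <- array(mu, c(1, 1, d[3], d[4]))
  if (!ctx$rec) return(list(v = out))
  ag_node(out, ctx, bw = function(g) {
    ag_acc(x, array(rep(as.vector(g) / (d[1] * d[2]), each = d[1] * d[2]), d))
  })
}

ag_gmp <- function(x, ctx) {
  d <- dim(x$v)
  hw <- d[1] * d[2]
  M <- matrix(x$v, hw, d[3] * d[4])
  am <- max.col(t(M), ties.method = "first")
  vals <- M[cbind(am, seq_len(ncol(M)))]
  out <- array(vals, c(1, 1, d[3], d[4]))
  if (!ctx$rec) return(list(v = out))
  ag_node(out, ctx, bw = function(g) {
    gM <- matrix(0, hw, d[3] * d[4])
    gM[cbind(am, seq_len(ncol(gM)))] <- as.vector(g)
    ag_acc(x, array(gM, d))
  })
}

# channel-wise mean and max per pixel -> (H, W, 2, N)
ag_chpool <- function(x, ctx) {
  d <- dim(x$v)
  hw <- d[1] * d[2]
  out <- array(0, c(d[1], d[2], 2, d[4]))
  amx <- matrix(0L, hw, d[4])
  for (n in seq_len(d[4])) {
    M <- matrix(x$v[, , , n], hw, d[3])
    out[, , 1, n] <- rowMeans(M)
    best <- M[, 1]
    bi <- rep(1L, hw)
    if (d[3] > 1) for (c in 2:d[3]) {
      upd <- M[, c] > best
      best[upd] <- M[upd, c]
      bi[upd] <- c
    }
    out[, , 2, n] <- best
    amx[, n] <- bi
  }
  if (!ctx$rec) return(list(v = out))
  ag_node(out, ctx, bw = function(g) {
    gx <- array(0, d)
    for (n in seq_len(d[4])) {
      gM <- matrix(rep(as.vector(g[, , 1, n]) / d[3], d[3]), hw, d[3])
      gmax <- as.vector(g[, , 2, n])
      gM[cbind(seq_len(hw), amx[, n])] <- gM[cbind(seq_len(hw), amx[, n])] + gmax
      gx[, , , n] <- array(gM, c(d[1], d[2], d[3]))
    }
    ag_acc(x, gx)
  })
}

ag_act <- function(x, kind, ctx) {
  code <- act_code(kind)
  out <- act_fw(x$v, code)
  if (!ctx$rec) return(list(v = out))
  ag_node(out, ctx, bw = function(g) ag_acc(x, act_bw(x$v, g, code)))
}

# general broadcast multiply: dims of a$v are either equal to dims of x$v or 1
ag_mul_bc <- function(x, a, ctx) {
  d <- dim(x$v)
  da <- dim(a$v)
  ix <- lapply(1:4, function(i) if (da[i] == 1L) rep(1L, d[i]) else seq_len(d[i]))
  ae <- a$v[ix[[1]], ix[[2]], ix[[3]], ix[[4]], drop = FALSE]
  out <- x$v * ae
  if (!ctx$rec) return(list(v = out))
  ag_node(out, ctx, bw = function(g) {
    ag_acc(x, g * ae)
    ga_full <- g * x$v
    red <- which(da == 1L & d > 1L)
    ga <- if (length(red) == 0) ga_full else {
      if (identical(red, c(1L, 2L))) {
        array(.colSums(ga_full, d[1] * d[2], d[3] * d[4]), c(1, 1, d[3], d[4]))
      } else if (identical(red, 3L)) {
        out3 <- array(0, c(d[1], d[2], 1, d[4]))
        for (n in seq_len(d[4]))
          out3[, , 1, n] <- rowSums(matrix(ga_full[, , , n], d[1] * d[2], d[3]))
        out3
      } else {
        apply(ga_full, which(da > 1L | d == 1L), sum) -> s
        array(s, da)
      }
    }
    ag_acc(a, ga)
  })
}

# mean over the width axis -> (H, 1, C, N)
ag_pool_w <- function(x, ctx) {
  d <- dim(x$v)
  A <- array(x$v, c(d[1], d[2], d[3] * d[4]))
  out <- array(0, c(d[1], 1, d[3], d[4]))
  acc <- matrix(0, d[1], d[3] * d[4])
  for (w in seq_len(d[2])) acc <- acc + A[, w, ]
  out[, 1, , ] <- acc / d[2]
  if (!ctx$rec) return(list(v = out))
  ag_node(out, ctx, bw = function(g) {
    gx <- array(g[, rep(1L, d[2]), , , drop = FALSE] / d[2], d)
    ag_acc(x, gx)
  })
}

# mean over the height axis, transposed so the strip lies along dim 1:
# (1, W, C, N) stored as (W, 1, C, N)
ag_pool_h <- function(x, ctx) {
  d <- dim(x$v)
  cm <- .colMeans(x$v, d[1], d[2] * d[3] * d[4])
  out <- array(cm, c(d[2], 1, d[3], d[4]))
  if (!ctx$rec) return(list(v = out))
  ag_node(out, ctx, bw = function(g) {
    gv <- array(as.vector(g), c(d[2], d[3], d[4]))
    gx <- array(rep(as.vector(gv), each = d[1]) / d[1], d)
    ag_acc(x, gx)
  })
}

# take a contiguous row range (used to split the coordinate-attention strip)
ag_slice_rows <- function(x, rows, ctx) {
  d <- dim(x$v)
  out <- x$v[rows, , , , drop = FALSE]
  if (!ctx$rec) return(list(v = out))
  ag_node(out, ctx, bw = function(g) {
    gx <- array(0, d)
    gx[rows, , , ] <- g
    ag_acc(x, gx)
  })
}

# concatenate strips along the height axis (dims 2..4 must agree)
ag_cat_rows <- function(xs, ctx) {
  ds <- lapply(xs, function(x) dim(x$v))
  hh <- vapply(ds, `[`, 0, 1L)
  d1 <- ds[[1]]
  out <- array(0, c(sum(hh), d1[2], d1[3], d1[4]))
  off <- 0L
  for (i in seq_along(xs)) {
    out[off + seq_len(hh[i]), , , ] <- xs[[i]]$v
    off <- off + hh[i]
  }
  if (!ctx$rec) return(list(v = out))
  ag_node(out, ctx, bw = function(g) {
    off <- 0L
    for (i in seq_along(xs)) {
      ag_acc(xs[[i]], g[off + seq_len(hh[i]), , , , drop = FALSE])
      off <- off + hh[i]
    }
  })
}

# transpose a (W, 1, C, N) strip into (1, W, C, N)
ag_transpose_strip <- function(x, ctx) {
  d <- dim(x$v)
  out <- array(as.vector(x$v), c(1, d[1], d[3], d[4]))
  if (!ctx$rec) return(list(v = out))
  ag_node(out, ctx, bw = function(g) {
    ag_acc(x, array(as.vector(g), d))
  })
}
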