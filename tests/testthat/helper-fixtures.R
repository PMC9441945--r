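# Shared fixtures: tiny tensors, small models and seeded scenes built in
# code at test time.

rand_fmap <- function(h = 8, w = 8, c = 16, n = 2, seed = 1) {
  set.seed(seed)
  array(stats::runif(h * w * c * n), c(h, w, c, n))
}

# narrow model used where a full-width build would be wasteful
tiny_model <- function(variant = "mga-yolo", nc = 4, width = 0.25) {
  set.seed(99)
  build_model(mga_config(variant, nc = nc, width_multiple = width))
}

# run one block forward in eval mode on a plain array
blk_eval <- function(blk, x) {
  ctx <- mgayolo:::ag_ctx(training = FALSE)
  mgayolo:::blk_fwd(blk, mgayolo:::ag_input(x, ctx), ctx)$v
}

# finite-difference gradient check of a block; returns worst relative error
gradcheck_block <- function(make_block, d_in, eps = 1e-3, n_probe = 2,
                            seed = 1) {
  set.seed(seed)
  blk <- make_block()
  x <- array(stats::runif(prod(d_in)), d_in)
  W <- NULL
  run <- function() {
    ctx <- mgayolo:::ag_ctx(training = TRUE)
    out <- mgayolo:::blk_fwd(blk, mgayolo:::ag_input(x, ctx), ctx)
    if (is.null(W)) W <<- array(stats::rnorm(length(out$v)), dim(out$v))
    list(L = sum(out$v * W), out = out, ctx = ctx)
  }
  r <- run()
  r$out$grad <- W
  mgayolo:::ag_backward(r$ctx)
  leaves <- list()
  mgayolo:::module_walk(blk, function(l) leaves[[length(leaves) + 1]] <<- l)
  worst <- 0
  for (l in leaves) for (fld in c("w", "gamma", "beta", "b")) {
    if (is.null(l[[fld]])) next
    gf <- l[[paste0("g", fld)]]
    for (rep in seq_len(n_probe)) {
      i <- sample(length(l[[fld]]), 1)
      v0 <- l[[fld]][i]
      l[[fld]][i] <- v0 + eps
      lp <- run()$L
      l[[fld]][i] <- v0 - eps
      lm <- run()$L
      l[[fld]][i] <- v0
      gn <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(gf[i] - gn) / max(abs(gn), abs(gf[i]), 1e-4))
    }
  }
  worst
}

# small detection/ground-truth tables
det_df <- function(...) {
  d <- data.frame(...)
  if (is.null(d$image)) d$image <- 1L
  d
}

# Independent naive reference implementation of evaluate_detections
# (the metric oracle): scalar IoU, greedy confidence-ordered matching by
# exhaustive per-detection scans over the remaining ground truths, and
# interpolated AP computed as a direct maximum over the anchored
# precision-recall points rather than a precomputed envelope.  Shares no
# code with the package implementation.
oracle_evaluate <- function(dets, gts, nc, thrs = seq(0.5, 0.95, by = 0.05)) {
  iou1 <- function(a, b) {
    iw <- min(a[3], b[3]) - max(a[1], b[1])
    ih <- min(a[4], b[4]) - max(a[2], b[2])
    if (iw <= 0 || ih <= 0) return(0)
    inter <- iw * ih
    inter / ((a[3] - a[1]) * (a[4] - a[2]) +
             (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  cols <- c("x1", "y1", "x2", "y2")
  ap50 <- map <- prec <- rec <- rep(NA_real_, nc)
  for (cl in seq_len(nc) - 1L) {
    dc <- dets[dets$class_id == cl, , drop = FALSE]
    dc <- dc[order(-dc$confidence), , drop = FALSE]
    gc <- gts[gts$class_id == cl, , drop = FALSE]
    n_gt <- nrow(gc)
    nd <- nrow(dc)
    aps <- numeric(length(thrs))
    tp50 <- 0
    for (t in seq_along(thrs)) {
      tp <- logical(nd)
      used <- logical(n_gt)
      for (i in seq_len(nd)) {
        best <- -1
        bj <- 0L
        for (j in seq_len(n_gt)) {
          if (used[j] || gc$image[j] != dc$image[i]) next
          v <- iou1(as.numeric(dc[i, cols]), as.numeric(gc[j, cols]))
          if (v >= thrs[t] && v > best) { best <- v; bj <- j }
        }
        if (bj > 0L) { used[bj] <- TRUE; tp[i] <- TRUE }
      }
      aps[t] <- if (n_gt == 0) NA_real_ else if (nd == 0 || !any(tp)) 0 else {
        ctp <- cumsum(tp)
        rc <- ctp / n_gt
        pr <- ctp / seq_len(nd)
        mean(vapply(seq(0, 1, by = 0.01), function(r)
          max(c(if (r <= 0) 1, pr[rc >= r], 0)), numeric(1)))
      }
      if (t == 1) tp50 <- sum(tp)
    }
    if (n_gt > 0) { ap50[cl + 1] <- aps[1]; map[cl + 1] <- mean(aps) }
    prec[cl + 1] <- if (nd > 0) tp50 / nd else if (n_gt > 0) 0 else NA_real_
    rec[cl + 1] <- if (n_gt > 0) tp50 / n_gt else NA_real_
  }
  v <- !is.na(map)
  list(precision = mean(prec[v]), recall = mean(rec[v]),
       ap50 = mean(ap50[v]), map = mean(map[v]))
}

# random small multi-image, multi-class evaluation instance (<= 4 boxes
# per image) with contention: some ground truths drawn twice, some missed,
# plus unmatched noise detections
random_eval_instance <- function(nc = 3, n_images = 2) {
  gts <- do.call(rbind, lapply(seq_len(n_images), function(im) {
    ng <- sample(1:4, 1)
    g <- data.frame(image = im, class_id = sample(seq_len(nc) - 1L, ng, TRUE),
                    x1 = runif(ng, 0, 60), y1 = runif(ng, 0, 60))
    g$x2 <- g$x1 + runif(ng, 8, 25)
    g$y2 <- g$y1 + runif(ng, 8, 25)
    g
  }))
  dets <- do.call(rbind, lapply(seq_len(n_images), function(im) {
    g <- gts[gts$image == im, , drop = FALSE]
    nd <- sample(1:4, 1)
    pick <- sample(nrow(g), nd, replace = TRUE)
    d <- g[pick, , drop = FALSE]
    pert <- matrix(runif(4 * nd, -4, 4), nd)
    d$x1 <- d$x1 + pert[, 1]; d$y1 <- d$y1 + pert[, 2]
    d$x2 <- pmax(d$x2 + pert[, 3], d$x1 + 1)
    d$y2 <- pmax(d$y2 + pert[, 4], d$y1 + 1)
    # occasionally predict the wrong class
    flip <- runif(nd) < 0.2
    d$class_id[flip] <- (d$class_id[flip] + 1L) %% nc
    d$confidence <- runif(nd)
    d
  }))
  list(dets = dets, gts = gts)
}
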