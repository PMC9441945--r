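#' Training configuration
#'
#' Defaults follow the detector family's standard setup: SGD with initial learning
#' rate `lr0 = 0.01` decayed each epoch by a one-cycle cosine multiplier down
#' to `lr0 * lrf` with `lrf = 0.2`, momentum 0.937 and weight decay 5e-4.
#'
#' @param lr0 initial learning rate.
#' @param lrf final learning-rate fraction (final lr is `lr0 * lrf`).
#' @param epochs training epochs.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty on convolution weights.
#' @param batch batch size.
#' @param img_size square input edge length (multiple of the model's largest
#'   stride).
#' @param warmup_epochs linear learning-rate ramp at the start.
#' @param seed RNG seed controlling batching and any augmentation.
#' @param loss_gains loss-term weights passed to [compute_loss()].
#' @return a `train_config` list.
#' @export
train_config <- function(lr0 = 0.01, lrf = 0.2, epochs = 50, momentum = 0.937,
                         weight_decay = 5e-4, batch = 4, img_size = 640,
                         warmup_epochs = 3, seed = 0,
                         loss_gains = c(box = 0.05, obj = 1.0, cls = 0.5)) {
  stopifnot(lr0 > 0, lrf > 0, lrf <= 1)
  structure(list(lr0 = lr0, lrf = lrf, epochs = epochs, momentum = momentum,
                 weight_decay = weight_decay, batch = batch,
                 img_size = img_size, warmup_epochs = warmup_epochs,
                 seed = seed, loss_gains = loss_gains),
            class = "train_config")
}

#' One-cycle cosine learning rate at a given epoch
#'
#' `lr(x) = lr0 * ((1 - cos(pi x / epochs)) / 2 * (lrf - 1) + 1)`, so
#' `lr(0) = lr0` and `lr(epochs) = lr0 * lrf`.  The multiplier is applied to
#' the base rate each epoch, not cumulatively.
#'
#' @param epoch epoch index in `[0, epochs]`.
#' @param cfg a [train_config()].
#' @return the learning rate (numeric scalar).
#' @examples
#' lr_at(0, train_config(epochs = 10))   # 0.01
#' lr_at(10, train_config(epochs = 10))  # 0.002
#' @export
lr_at <- function(epoch, cfg) {
  if (cfg$epochs == 0) stop("epochs must be positive")
  stopifnot(epoch >= 0, epoch <= cfg$epochs)
  lf <- (1 - cos(pi * epoch / cfg$epochs)) / 2 * (cfg$lrf - 1) + 1
  cfg$lr0 * lf
}

# ---- target assignment ---------------------------------------------------

# YOLOv5-style multi-anchor assignment: an object is assigned to every
# anchor of a head whose width/height ratio to the target is within a factor
# of 4, in its own cell and up to two neighbouring cells on the near side.
# `targets`: data frame image (1-based), class_id (0-based), cx, cy, w, h in
# input pixels.  Returns one assignment table per head.
build_targets <- function(model, targets, img_size) {
  nl <- length(model$strides)
  out <- vector("list", nl)
  for (h in seq_len(nl)) {
    stride <- model$strides[h]
    anc <- matrix(model$cfg$anchors[[h]], nrow = 2) / stride  # grid units
    na <- ncol(anc)
    gsize <- img_size %/% stride
    rows <- list()
    if (nrow(targets) > 0) {
      for (a in seq_len(na)) {
        gw <- targets$w / stride
        gh <- targets$h / stride
        r1 <- gw / anc[1, a]
        r2 <- gh / anc[2, a]
        ok <- pmax(r1, 1 / r1, r2, 1 / r2) < 4
        if (!any(ok)) next
        t <- targets[ok, , drop = FALSE]
        gx <- t$cx / stride
        gy <- t$cy / stride
        base <- data.frame(image = t$image, class_id = t$class_id,
                           anchor = a, gx = gx, gy = gy,
                           gw = t$w / stride, gh = t$h / stride)
        off <- list(c(0, 0))
        fx <- gx - floor(gx)
        fy <- gy - floor(gy)
        cand <- list(left = fx < 0.5 & gx > 1, up = fy < 0.5 & gy > 1,
                     right = fx >= 0.5 & gx < gsize - 1,
                     down = fy >= 0.5 & gy < gsize - 1)
        offs <- list(left = c(-1, 0), up = c(0, -1), right = c(1, 0),
                     down = c(0, 1))
        sel <- list(base)
        for (nm in names(cand)) {
          if (any(cand[[nm]])) {
            nb <- base[cand[[nm]], , drop = FALSE]
            nb$gi_off <- offs[[nm]][1]
            nb$gj_off <- offs[[nm]][2]
            sel[[length(sel) + 1]] <- nb
          }
        }
        base$gi_off <- 0
        base$gj_off <- 0
        sel[[1]] <- base
        rows[[length(rows) + 1]] <- do.call(rbind, sel)
      }
    }
    if (length(rows) > 0) {
      tab <- do.call(rbind, rows)
      tab$gi <- floor(tab$gx) + tab$gi_off      # 0-based cell column
      tab$gj <- floor(tab$gy) + tab$gj_off      # 0-based cell row
      tab <- tab[tab$gi >= 0 & tab$gi < gsize & tab$gj >= 0 & tab$gj < gsize, ,
                 drop = FALSE]
      out[[h]] <- tab
    } else {
      out[[h]] <- data.frame()
    }
  }
  out
}

# complete IoU of two boxes given as (cx, cy, w, h); scalar
ciou_xywh <- function(p, t) {
  eps <- 1e-9
  b1 <- c(p[1] - p[3] / 2, p[2] - p[4] / 2, p[1] + p[3] / 2, p[2] + p[4] / 2)
  b2 <- c(t[1] - t[3] / 2, t[2] - t[4] / 2, t[1] + t[3] / 2, t[2] + t[4] / 2)
  iw <- pmax(min(b1[3], b2[3]) - max(b1[1], b2[1]), 0)
  ih <- pmax(min(b1[4], b2[4]) - max(b1[2], b2[2]), 0)
  inter <- iw * ih
  union <- p[3] * p[4] + t[3] * t[4] - inter + eps
  iou <- inter / union
  cw <- max(b1[3], b2[3]) - min(b1[1], b2[1])
  ch <- max(b1[4], b2[4]) - min(b1[2], b2[2])
  c2 <- cw^2 + ch^2 + eps
  rho2 <- (p[1] - t[1])^2 + (p[2] - t[2])^2
  v <- (4 / pi^2) * (atan(t[3] / (t[4] + eps)) - atan(p[3] / (p[4] + eps)))^2
  alpha <- v / (v - iou + 1 + eps)
  iou - rho2 / c2 - alpha * v
}

bce <- function(logit, target) {
  # numerically stable binary cross-entropy with logits
  pmax(logit, 0) - logit * target + log1p(exp(-abs(logit)))
}

#' Composite detection loss
#'
#' CIoU box regression on assigned cells, binary cross-entropy objectness
#' over every cell with per-head balance weights, and binary cross-entropy
#' classification — the standard anchor-based one-stage composite.  Gradients
#' with respect to the raw head maps are returned alongside the values so the
#' training loop can seed backpropagation; box-term gradients are obtained by
#' central finite differences of the CIoU, and the returned gradients carry
#' the conventional batch-size scaling of the backward signal.
#'
#' @param preds list of raw head arrays (values, not nodes).
#' @param targets data frame `image, class_id, cx, cy, w, h` in input pixels.
#' @param model the `mga_model`.
#' @param img_size input edge length used for this batch.
#' @param want_grads also return per-head gradient arrays.
#' @param gains loss-term weights `c(box, obj, cls)`, each rescaled by
#'   `3/nl`.  Two COCO-calibrated renormalisations are deliberately omitted:
#'   the `nc/80` factor on the classification weight (at 4 classes it would
#'   shrink the class gradient twenty-fold) and the `(img/640)^2` factor on
#'   the objectness weight (our scenes carry a roughly constant object count
#'   per image, not a constant object density per pixel).
#' @return list with `box`, `obj`, `cls`, `total` (and `grads`).
#' @export
compute_loss <- function(preds, targets, model, img_size, want_grads = FALSE,
                         gains = c(box = 0.05, obj = 1.0, cls = 0.5)) {
  nl <- length(preds)
  nc <- model$nc
  no <- nc + 5L
  balance <- if (nl == 4) c(4.0, 1.0, 0.25, 0.06) else c(4.0, 1.0, 0.4)
  gain_box <- gains[[1]] * 3 / nl
  gain_obj <- gains[[2]] * 3 / nl
  gain_cls <- gains[[3]] * 3 / nl
  assigns <- build_targets(model, targets, img_size)
  lbox <- lobj <- lcls <- 0
  nbox <- ncls <- 0
  grads <- if (want_grads) lapply(preds, function(p) array(0, dim(p))) else NULL
  for (h in seq_len(nl)) {
    p <- preds[[h]]
    d <- dim(p)
    tobj <- array(0, c(d[1], d[2], d[3] %/% no, d[4]))
    tab <- assigns[[h]]
    anc <- matrix(model$cfg$anchors[[h]], nrow = 2) / model$strides[h]
    if (nrow(tab) > 0) {
      for (r in seq_len(nrow(tab))) {
        gi <- tab$gi[r]; gj <- tab$gj[r]; a <- tab$anchor[r]; b <- tab$image[r]
        ch0 <- (a - 1) * no
        pv <- p[gj + 1, gi + 1, ch0 + 1:4, b]
        dec <- function(pv) {
          c((2 * stats::plogis(pv[1]) - 0.5) + gi,
            (2 * stats::plogis(pv[2]) - 0.5) + gj,
            (2 * stats::plogis(pv[3]))^2 * anc[1, a],
            (2 * stats::plogis(pv[4]))^2 * anc[2, a])
        }
        tb <- c(tab$gx[r], tab$gy[r], tab$gw[r], tab$gh[r])
        ci <- ciou_xywh(dec(pv), tb)
        lbox <- lbox + (1 - ci)
        nbox <- nbox + 1
        tobj[gj + 1, gi + 1, a, b] <- max(tobj[gj + 1, gi + 1, a, b],
                                          max(min(ci, 1), 0))
        # classification targets
        cl <- tab$class_id[r]
        logits <- p[gj + 1, gi + 1, ch0 + 5 + seq_len(nc), b]
        tvec <- as.numeric(seq_len(nc) - 1 == cl)
        lcls <- lcls + sum(bce(logits, tvec))
        ncls <- ncls + nc
        if (want_grads) {
          # box gradient by central differences through the CIoU
          gb <- numeric(4)
          eps <- 1e-4
          for (q in 1:4) {
            pv_p <- pv; pv_p[q] <- pv_p[q] + eps
            pv_m <- pv; pv_m[q] <- pv_m[q] - eps
            gb[q] <- (ciou_xywh(dec(pv_m), tb) - ciou_xywh(dec(pv_p), tb)) /
              (2 * eps)
          }
          grads[[h]][gj + 1, gi + 1, ch0 + 1:4, b] <-
            grads[[h]][gj + 1, gi + 1, ch0 + 1:4, b] + gb
          grads[[h]][gj + 1, gi + 1, ch0 + 5 + seq_len(nc), b] <-
            grads[[h]][gj + 1, gi + 1, ch0 + 5 + seq_len(nc), b] +
            (stats::plogis(logits) - tvec)
        }
      }
    }
    obj_idx <- rep(seq_len(d[3] %/% no) - 1, each = 1) * no + 5
    pobj <- p[, , obj_idx, , drop = FALSE]
    lobj <- lobj + balance[h] * mean(bce(pobj, tobj))
    if (want_grads) {
      gobj <- balance[h] * (stats::plogis(pobj) - tobj) / length(pobj)
      grads[[h]][, , obj_idx, ] <-
        grads[[h]][, , obj_idx, , drop = FALSE] + gobj
    }
  }
  lbox <- if (nbox > 0) lbox / nbox else 0
  lcls <- if (ncls > 0) lcls / ncls else 0
  if (want_grads) {
    # scale the raw per-term gradients by their gains and reductions; the
    # backward signal is additionally scaled by the batch size, matching the
    # usual one-stage training convention
    bs <- dim(preds[[1]])[4]
    for (h in seq_len(nl)) {
      d <- dim(preds[[h]])
      na_h <- d[3] %/% no
      sc <- array(gain_obj, d)  # objectness channels already include balance/N
      for (a in seq_len(na_h)) {
        box_ch <- (a - 1) * no + 1:4
        cls_ch <- (a - 1) * no + 5 + seq_len(nc)
        sc[, , box_ch, ] <- gain_box / max(nbox, 1)
        sc[, , cls_ch, ] <- gain_cls / max(ncls, 1)
      }
      grads[[h]] <- grads[[h]] * (bs * sc)
    }
  }
  total <- gain_box * lbox + gain_obj * lobj + gain_cls * lcls
  if (!is.finite(total))
    stop("loss diverged to a non-finite value; aborting with diagnostics: ",
         "box=", lbox, " obj=", lobj, " cls=", lcls)
  out <- list(box = gain_box * lbox, obj = gain_obj * lobj,
              cls = gain_cls * lcls, total = total)
  if (want_grads) out$grads <- grads
  out
}

# annotated images -> target table in pixels of the (already letterboxed)
# canvas
targets_from_items <- function(items) {
  rows <- lapply(seq_along(items), function(i) {
    ai <- items[[i]]
    if (nrow(ai$boxes) == 0) return(NULL)
    data.frame(image = i, class_id = ai$class_ids,
               cx = (ai$boxes[, 1] + ai$boxes[, 3]) / 2,
               cy = (ai$boxes[, 2] + ai$boxes[, 4]) / 2,
               w = ai$boxes[, 3] - ai$boxes[, 1],
               h = ai$boxes[, 4] - ai$boxes[, 2])
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(image = integer(), class_id = integer(), cx = numeric(),
                      cy = numeric(), w = numeric(), h = numeric()))
  do.call(rbind, rows)
}

#' Train a model with SGD and the one-cycle cosine schedule
#'
#' Desk-scale training loop: batches of letterboxed annotated images, SGD
#' with momentum, linear warmup followed by the [lr_at()] schedule, and a
#' per-epoch log of the learning rate and loss components.  Fixed seeds give
#' a reproducible loss trajectory on fixed data.
#'
#' @param model an `mga_model` (modified in place and returned).
#' @param items list of `annotated_image` objects whose images already match
#'   `cfg$img_size` (see [letterbox()] / [generate_scene()]).
#' @param cfg a [train_config()].
#' @param fliplr probability of horizontal flip augmentation per image.
#' @param verbose print one line per epoch.
#' @param hook optional `function(model, epoch)` run after each epoch; return
#'   `TRUE` to stop early (e.g. once a validation metric is reached).
#' @return the model, with the epoch log in `model$log`.
#' @export
fit_model <- function(model, items, cfg, fliplr = 0.5, verbose = FALSE,
                      hook = NULL) {
  stopifnot(length(items) > 0)
  log <- data.frame()
  n <- length(items)
  nb_epoch <- ceiling(n / cfg$batch)
  n_warm <- cfg$warmup_epochs * nb_epoch
  it <- 0
  for (epoch in seq_len(cfg$epochs)) {
    set.seed(cfg$seed * 10000 + epoch)
    lr_sched <- lr_at(epoch - 1, cfg)
    ord <- sample.int(n)
    ep <- c(box = 0, obj = 0, cls = 0, total = 0)
    nb <- 0
    for (start in seq(1, n, by = cfg$batch)) {
      idx <- ord[start:min(start + cfg$batch - 1, n)]
      batch_items <- lapply(items[idx], function(ai) {
        if (stats::runif(1) < fliplr) flip_item(ai) else ai
      })
      x <- array(0, c(cfg$img_size, cfg$img_size, 3, length(idx)))
      for (j in seq_along(batch_items)) x[, , , j] <- batch_items[[j]]$image
      tg <- targets_from_items(batch_items)
      ctx <- ag_ctx(training = TRUE)
      heads <- model_forward(model, x, training = TRUE, ctx = ctx)
      preds <- lapply(heads, function(nd) nd$v)
      ls <- compute_loss(preds, tg, model, cfg$img_size, want_grads = TRUE,
                         gains = cfg$loss_gains %||% c(0.05, 1.0, 0.5))
      if (ls$total > 1e4)
        stop("training diverged (loss ", round(ls$total, 2), ")")
      for (h in seq_along(heads)) heads[[h]]$grad <- ls$grads[[h]]
      ag_backward(ctx)
      it <- it + 1
      # per-iteration warmup: weight lr ramps from 0, bias lr from 0.1,
      # momentum from 0.8 to its nominal value
      if (it <= n_warm && n_warm > 0) {
        f <- it / n_warm
        lr_w <- f * lr_sched
        lr_b <- 0.1 + f * (lr_sched - 0.1)
        mom <- 0.8 + f * (cfg$momentum - 0.8)
      } else {
        lr_w <- lr_sched
        lr_b <- lr_sched
        mom <- cfg$momentum
      }
      sgd_step_model(model, lr_w, mom, cfg$weight_decay, lr_b)
      zero_grads_model(model)
      ep <- ep + c(ls$box, ls$obj, ls$cls, ls$total)
      nb <- nb + 1
    }
    lr <- lr_w
    log <- rbind(log, data.frame(epoch = epoch, lr = lr, box = ep[1] / nb,
                                 obj = ep[2] / nb, cls = ep[3] / nb,
                                 total = ep[4] / nb, row.names = NULL))
    model$log <- log
    if (verbose)
      cat(sprintf("epoch %3d  lr %.5f  box %.4f  obj %.4f  cls %.4f\n",
                  epoch, lr, ep[1] / nb, ep[2] / nb, ep[3] / nb))
    if (!is.null(hook) && isTRUE(hook(model, epoch))) break
  }
  model$log <- log
  model
}

sgd_step_model <- function(model, lr, momentum, wd, lr_bias = lr) {
  for (m in model$layers) sgd_step(m, lr, momentum, wd, lr_bias)
}

zero_grads_model <- function(model) {
  for (m in model$layers) zero_grads(m)
}

flip_item <- function(ai) {
  d <- dim(ai$image)
  ai$image <- ai$image[, rev(seq_len(d[2])), , drop = FALSE]
  if (nrow(ai$boxes) > 0) {
    x1 <- d[2] - ai$boxes[, 3]
    x2 <- d[2] - ai$boxes[, 1]
    ai$boxes[, 1] <- x1
    ai$boxes[, 3] <- x2
  }
  ai
}
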