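# Seeded generator of synthetic multi-leaf scenes.
#
# Scenes emulate the structure of field photographs of apple foliage: a
# cluttered soil/foliage background, several elliptical leaves at random
# poses, and per-class procedural lesion phenotypes — rust as small
# saturated orange dots, scab as dark olive blotches strung along a vein
# line, black rot as concentric "frog eye" ring spots, healthy leaves
# unmarked.  Every leaf gets a tight bounding box and a class id, so the
# whole detection pipeline (I/O, augmentation, training, evaluation) can be
# exercised without any external dataset.  The styles are deliberately
# high-contrast and linearly separable by lesion hue; see the methods
# vignette for what this does and does not demonstrate.

#' Scene specification
#'
#' @param canvas square edge length in pixels (at least 64).
#' @param n_leaves inclusive range (length-2 vector) of leaves per scene.
#' @param leaf_scale range of the leaf semi-major axis as a fraction of the
#'   canvas edge; the default gives mid-sized leaves, larger values give
#'   the big high-contrast targets used by the training demonstration.
#' @param background_clutter amount of background texture in \[0, 1\].
#' @param max_occlusion highest tolerated occluded fraction of any leaf.
#' @param seed base RNG seed.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(canvas = 256, n_leaves = c(2, 4),
                       leaf_scale = c(0.10, 0.16),
                       background_clutter = 0.5, max_occlusion = 0.5,
                       seed = 0) {
  if (canvas < 64) stop("canvas too small (minimum 64)")
  if (length(n_leaves) == 1) n_leaves <- c(n_leaves, n_leaves)
  if (length(leaf_scale) == 1) leaf_scale <- c(leaf_scale, leaf_scale)
  stopifnot(background_clutter >= 0, background_clutter <= 1,
            leaf_scale[1] > 0, leaf_scale[2] <= 0.45)
  structure(list(canvas = canvas, n_leaves = n_leaves,
                 leaf_scale = leaf_scale,
                 background_clutter = background_clutter,
                 max_occlusion = max_occlusion, seed = seed,
                 classes = default_classes()),
            class = "scene_spec")
}

# smooth random field in [0,1] built from a coarse grid blown up bilinearly
smooth_field <- function(n, coarse = 8) {
  g <- matrix(stats::runif(coarse^2), coarse, coarse)
  xi <- seq(1, coarse, length.out = n)
  lo <- pmax(floor(xi), 1)
  hi <- pmin(lo + 1, coarse)
  fr <- xi - lo
  rowm <- g[lo, , drop = FALSE] * (1 - fr) + g[hi, , drop = FALSE] * fr
  out <- rowm[, lo, drop = FALSE] * rep(1 - fr, each = n) +
    rowm[, hi, drop = FALSE] * rep(fr, each = n)
  out
}

#' Generate one synthetic multi-leaf scene
#'
#' @param spec a [scene_spec()].
#' @param seed RNG seed for this scene (defaults to `spec$seed`).
#' @param class_order optional integer vector of 0-based class ids assigned
#'   to the leaves in placement order (recycled); by default classes cycle
#'   with the seed so datasets of consecutive seeds come out balanced.
#' @return an [annotated_image()] with pixel data, one tight box and one
#'   class id per leaf.  Leaf placement retries until every leaf keeps at
#'   least `1 - max_occlusion` of its area visible.
#' @examples
#' sc <- generate_scene(scene_spec(canvas = 128), seed = 1)
#' nrow(sc$boxes)
#' @export
generate_scene <- function(spec, seed = spec$seed, class_order = NULL) {
  set.seed(seed)
  S <- spec$canvas
  n <- spec$n_leaves[1] +
    sample.int(spec$n_leaves[2] - spec$n_leaves[1] + 1L, 1) - 1L
  if (S < 16 * n)
    stop("canvas too small for ", n, " leaves")
  cl <- spec$background_clutter
  # background: brownish soil mottle with green speckle
  f1 <- smooth_field(S, 6)
  f2 <- smooth_field(S, 24)
  img <- array(0, c(S, S, 3))
  img[, , 1] <- 0.35 + cl * (0.25 * f1 - 0.1 * f2)
  img[, , 2] <- 0.30 + cl * (0.22 * f2 - 0.08 * f1)
  img[, , 3] <- 0.22 + cl * (0.15 * f1 * f2)
  if (cl > 0) {
    sp <- stats::runif(S * S) < 0.02 * cl
    img[, , 2][sp] <- img[, , 2][sp] + 0.25
  }
  xs <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)   # column coord
  ys <- matrix(rep(seq_len(S) - 0.5, times = S), S, S)  # row coord
  masks <- list()
  boxes <- matrix(0, 0, 4)
  classes <- integer()
  # classes cycle with the seed so large datasets come out balanced
  draw_order <- if (is.null(class_order)) (seed + seq_len(n) - 1L) %% 4L
    else rep_len(as.integer(class_order), n)
  for (li in seq_len(n)) {
    ok <- FALSE
    for (try in 1:60) {
      ls_rng <- spec$leaf_scale %||% c(0.10, 0.16)
      a <- stats::runif(1, ls_rng[1], ls_rng[2]) * S
      b <- a * stats::runif(1, 0.45, 0.7)
      th <- stats::runif(1, 0, pi)
      cx <- stats::runif(1, a, S - a)
      cy <- stats::runif(1, a, S - a)
      dx <- xs - cx
      dy <- ys - cy
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      m <- u^2 + v^2 <= 1
      # would this leaf occlude an earlier one too much?
      good <- TRUE
      for (pm in masks) {
        vis <- sum(pm$free & !m) / pm$area
        if (vis < 1 - spec$max_occlusion) { good <- FALSE; break }
      }
      if (!good) next
      cls_id <- draw_order[li]
      base_h <- 0.30 + stats::runif(1, -0.03, 0.03)  # green hue
      base_s <- 0.55 + stats::runif(1, -0.1, 0.1)
      base_v <- 0.52 + stats::runif(1, -0.08, 0.1)
      rgbm <- hsv_to_rgb(rbind(base_h, base_s, base_v))
      shade <- 1 - 0.25 * (u^2 + v^2)[m]  # radial shading
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[m] <- rgbm[ch] * shade
        img[, , ch] <- plane
      }
      img <- draw_vein(img, m, cx, cy, th, a, u, v)
      img <- draw_lesions(img, cls_id, m, cx, cy, th, a, b, u, v, xs, ys)
      for (j in seq_along(masks)) masks[[j]]$free <- masks[[j]]$free & !m
      masks[[length(masks) + 1]] <- list(free = m, area = sum(m))
      bb <- c(min(xs[m]) - 0.5, min(ys[m]) - 0.5,
              max(xs[m]) + 0.5, max(ys[m]) + 0.5)
      boxes <- rbind(boxes, pmin(pmax(bb, 0), S))
      classes <- c(classes, cls_id)
      ok <- TRUE
      break
    }
    if (!ok) next
  }
  annotated_image(pmin(pmax(img, 0), 1), boxes, classes,
                  sprintf("scene_%06d", seed))
}

draw_vein <- function(img, m, cx, cy, th, a, u, v) {
  vein <- m & abs(v) < 0.04 & abs(u) < 0.9
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[vein] <- plane[vein] * 0.8 + 0.08
    img[, , ch] <- plane
  }
  img
}

paint <- function(img, mask, rgb) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- rgb[ch]
    img[, , ch] <- plane
  }
  img
}

draw_lesions <- function(img, cls_id, m, cx, cy, th, a, b, u, v, xs, ys) {
  if (cls_id == 0) return(img)  # healthy
  if (cls_id == 1) {
    # rust: many small saturated orange dots
    k <- sample(14:24, 1)
    for (i in seq_len(k)) {
      ru <- sqrt(stats::runif(1, 0, 0.7))
      an <- stats::runif(1, 0, 2 * pi)
      pu <- ru * cos(an)
      pv <- ru * sin(an)
      px <- cx + (pu * a) * cos(th) - (pv * b) * sin(th)
      py <- cy + (pu * a) * sin(th) + (pv * b) * cos(th)
      r <- stats::runif(1, 0.03, 0.06) * a
      dot <- m & ((xs - px)^2 + (ys - py)^2 <= r^2)
      col <- hsv_to_rgb(rbind(0.07 + stats::runif(1, -0.01, 0.01), 0.95,
                              0.9))
      img <- paint(img, dot, col)
    }
  } else if (cls_id == 2) {
    # scab: dark olive blotches along the vein line
    k <- sample(5:8, 1)
    for (i in seq_len(k)) {
      pu <- stats::runif(1, -0.75, 0.75)
      pv <- stats::runif(1, -0.2, 0.2)
      px <- cx + (pu * a) * cos(th) - (pv * b) * sin(th)
      py <- cy + (pu * a) * sin(th) + (pv * b) * cos(th)
      r <- stats::runif(1, 0.09, 0.16) * a
      rr <- (xs - px)^2 + (ys - py)^2
      blotch <- m & rr <= r^2 * (0.7 + 0.6 * smoothness(xs, ys, px, py))
      col <- hsv_to_rgb(rbind(0.21 + stats::runif(1, -0.02, 0.02), 0.8,
                              0.16))
      img <- paint(img, blotch, col)
    }
  } else {
    # black rot: concentric-ring "frog eye" spots
    k <- sample(3:5, 1)
    for (i in seq_len(k)) {
      pu <- stats::runif(1, -0.6, 0.6)
      pv <- stats::runif(1, -0.6, 0.6)
      if (pu^2 + pv^2 > 0.7) next
      px <- cx + (pu * a) * cos(th) - (pv * b) * sin(th)
      py <- cy + (pu * a) * sin(th) + (pv * b) * cos(th)
      r <- stats::runif(1, 0.08, 0.14) * a
      dist <- sqrt((xs - px)^2 + (ys - py)^2)
      centre <- m & dist <= 0.45 * r
      ring1 <- m & dist > 0.45 * r & dist <= 0.75 * r
      ring2 <- m & dist > 0.75 * r & dist <= r
      img <- paint(img, centre, c(0.55, 0.45, 0.35))  # light brown-grey
      img <- paint(img, ring1, c(0.25, 0.12, 0.08))   # dark brown ring
      img <- paint(img, ring2, c(0.45, 0.20, 0.35))   # purple margin
    }
  }
  img
}

smoothness <- function(xs, ys, px, py) {
  0.5 + 0.5 * sin(0.35 * (xs - px)) * cos(0.3 * (ys - py))
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` scenes as PNG plus annotations in the requested format,
#' split into train/validation/test manifests.  Leaf classes are drawn from
#' a balanced pool so per-class label counts stay within a few percent of
#' each other.
#'
#' @param n_images number of scenes.
#' @param spec a [scene_spec()].
#' @param outdir output directory.
#' @param format annotation format (see [write_annotations()]).
#' @param split train/val/test fractions summing to 1.
#' @param seed base seed; scene `i` uses `seed + i`.
#' @return data frame manifest (`source_id`, `split`, label counts), also
#'   written to `outdir/manifest.tsv` and per-split `*.txt` lists.
#' @export
generate_dataset <- function(n_images, spec = scene_spec(), outdir,
                             format = "yolo_txt",
                             split = c(train = 0.54, val = 0.23, test = 0.23),
                             seed = 0) {
  if (abs(sum(split) - 1) > 1e-6) stop("split ratios must sum to 1")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  # leaf classes come from one global cycling pool so the per-class label
  # counts of the whole dataset stay balanced
  pool_pos <- 0L
  scenes <- lapply(seq_len(n_images), function(i) {
    order_i <- (pool_pos + seq_len(spec$n_leaves[2]) - 1L) %% 4L
    sc <- generate_scene(spec, seed = seed + i, class_order = order_i)
    pool_pos <<- pool_pos + length(sc$class_ids)
    sc$source_id <- sprintf("scene_%06d", i)
    sc
  })
  write_annotations(scenes, outdir, format)
  n_tr <- round(n_images * split[1])
  n_va <- round(n_images * split[2])
  assign <- rep(c("train", "val", "test"),
                c(n_tr, n_va, n_images - n_tr - n_va))
  ids <- vapply(scenes, `[[`, "", "source_id")
  counts <- t(vapply(scenes, function(s)
    tabulate(s$class_ids + 1, 4), numeric(4)))
  colnames(counts) <- default_classes()
  manifest <- data.frame(source_id = ids, split = assign, counts)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (sp in unique(assign))
    writeLines(ids[assign == sp], file.path(outdir, paste0(sp, ".txt")))
  manifest
}
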