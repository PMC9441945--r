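#' Intersection over union of axis-aligned boxes
#'
#' Boxes are pixel-space `(x1, y1, x2, y2)` with `x1 < x2`, `y1 < y2`.
#' Inputs may be single boxes (length-4 vectors) or n x 4 matrices; the
#' result is the IoU matrix of all pairs (dropped to a scalar for two single
#' boxes).
#'
#' @param a,b length-4 numeric vectors or n x 4 / m x 4 matrices.
#' @return numeric scalar or n x m matrix in \[0, 1\].
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
#' @export
box_iou <- function(a, b) {
  a <- rbind(a)
  b <- rbind(b)
  if (any(a[, 3] <= a[, 1]) || any(a[, 4] <= a[, 2]) ||
      any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2]))
    stop("degenerate box: area must be positive")
  iw <- pmax(outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax), 0)
  ih <- pmax(outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax), 0)
  inter <- iw * ih
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  res <- inter / (outer(area_a, area_b, `+`) - inter)
  if (nrow(a) == 1 && nrow(b) == 1) res[1, 1] else res
}

#' Non-maximum suppression
#'
#' Greedy per-class suppression: within each class, keep the
#' highest-confidence box and drop every remaining same-class box whose IoU
#' with it exceeds `iou_thr`; repeat.  Boxes of different classes never
#' suppress each other.  Output is sorted by descending confidence.
#'
#' @param dets data frame with columns `class_id`, `confidence`, `x1`, `y1`,
#'   `x2`, `y2` (extra columns such as `image` are preserved; when an
#'   `image` column is present suppression is also scoped per image).
#' @param iou_thr suppression threshold in \[0, 1\].
#' @return the surviving subset of `dets`, confidence-sorted.
#' @export
nms_boxes <- function(dets, iou_thr = 0.45) {
  if (iou_thr < 0 || iou_thr > 1) stop("iou_thr must be in [0, 1]")
  if (nrow(dets) == 0) return(dets)
  img <- if ("image" %in% names(dets)) dets$image else rep(1L, nrow(dets))
  keep <- logical(nrow(dets))
  for (grp in split(seq_len(nrow(dets)),
                    interaction(img, dets$class_id, drop = TRUE))) {
    ord <- grp[order(-dets$confidence[grp])]
    while (length(ord) > 0) {
      i <- ord[1]
      keep[i] <- TRUE
      ord <- ord[-1]
      if (length(ord) > 0) {
        ious <- box_iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                        as.matrix(dets[ord, c("x1", "y1", "x2", "y2")]))
        ord <- ord[as.vector(ious) <= iou_thr]
      }
    }
  }
  out <- dets[keep, , drop = FALSE]
  out[order(-out$confidence), , drop = FALSE]
}

# greedy confidence-ordered matching of one class in one image; returns a
# logical TP flag per detection (in the given order) for each IoU threshold
match_greedy <- function(db, gb, thrs) {
  nd <- nrow(db)
  ng <- nrow(gb)
  tp <- matrix(FALSE, nd, length(thrs))
  if (nd == 0 || ng == 0) return(tp)
  iou <- matrix(box_iou(db, gb), nd, ng)
  for (t in seq_along(thrs)) {
    used <- logical(ng)
    for (i in seq_len(nd)) {
      cand <- which(!used & iou[i, ] >= thrs[t])
      if (length(cand) > 0) {
        j <- cand[which.max(iou[i, cand])]
        used[j] <- TRUE
        tp[i, t] <- TRUE
      }
    }
  }
  tp
}

# COCO-style 101-point interpolated average precision from TP flags sorted
# by descending confidence
ap_from_tp <- function(tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(tp) == 0 || !any(tp)) return(0)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  # precision envelope, then mean over 101 recall points
  rc <- c(0, recall, 1)
  pr <- c(1, precision, 0)
  for (i in rev(seq_along(pr))[-1]) pr[i] <- max(pr[i], pr[i + 1])
  mean(vapply(seq(0, 1, by = 0.01), function(r) {
    idx <- which(rc >= r)
    if (length(idx) == 0) 0 else pr[min(idx)]
  }, numeric(1)))
}

#' Evaluate detections against ground truth
#'
#' Greedy confidence-ordered matching of detections to unmatched ground
#' truths at each IoU threshold, COCO-style interpolated average precision,
#' `ap50` at threshold 0.5 and `map` as the mean over thresholds
#' 0.50–0.95 (step 0.05).  Precision and recall are reported at the operating
#' point of the supplied detection set (IoU 0.5).  Per-class values are
#' averaged unweighted into the aggregate; classes without labels are
#' reported `NA` and excluded from means.
#'
#' @param dets data frame `image, class_id, confidence, x1, y1, x2, y2`.
#' @param gts data frame `image, class_id, x1, y1, x2, y2`.
#' @param iou_thresholds numeric vector of IoU thresholds.
#' @param nc number of classes (defaults to classes present in `gts`).
#' @return object of class `mga_eval`: `per_class` data frame and aggregate
#'   `precision`, `recall`, `ap50`, `map`.
#' @export
evaluate_detections <- function(dets, gts,
                                iou_thresholds = seq(0.5, 0.95, by = 0.05),
                                nc = NULL) {
  if (is.null(nc)) nc <- max(c(gts$class_id, dets$class_id, 0)) + 1
  cols <- c("x1", "y1", "x2", "y2")
  per <- vector("list", nc)
  for (cl in seq_len(nc) - 1L) {
    dc <- dets[dets$class_id == cl, , drop = FALSE]
    dc <- dc[order(-dc$confidence), , drop = FALSE]
    gc <- gts[gts$class_id == cl, , drop = FALSE]
    n_gt <- nrow(gc)
    tp <- matrix(FALSE, nrow(dc), length(iou_thresholds))
    if (nrow(dc) > 0) {
      for (im in unique(dc$image)) {
        sel <- which(dc$image == im)
        tp[sel, ] <- match_greedy(as.matrix(dc[sel, cols, drop = FALSE]),
                                  as.matrix(gc[gc$image == im, cols,
                                               drop = FALSE]),
                                  iou_thresholds)
      }
    }
    aps <- vapply(seq_along(iou_thresholds),
                  function(t) ap_from_tp(tp[, t], n_gt), numeric(1))
    tp50 <- sum(tp[, 1])
    prec <- if (nrow(dc) > 0) tp50 / nrow(dc) else if (n_gt > 0) 0 else NA
    rec <- if (n_gt > 0) tp50 / n_gt else NA
    per[[cl + 1]] <- data.frame(
      class_id = cl, labels = n_gt, precision = prec, recall = rec,
      ap50 = if (n_gt == 0) NA else aps[1],
      map = if (n_gt == 0) NA else mean(aps))
  }
  per_class <- do.call(rbind, per)
  valid <- !is.na(per_class$map)
  out <- list(per_class = per_class,
              precision = mean(per_class$precision[valid]),
              recall = mean(per_class$recall[valid]),
              ap50 = mean(per_class$ap50[valid]),
              map = mean(per_class$map[valid]))
  class(out) <- "mga_eval"
  out
}

#' @export
print.mga_eval <- function(x, ...) {
  cat(sprintf("detection evaluation: P %.3f  R %.3f  AP50 %.3f  mAP %.3f\n",
              x$precision, x$recall, x$ap50, x$map))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Detection confusion matrix
#'
#' Detections above `conf_thr` are matched per image to ground truths at IoU
#' `iou_thr` or better (regardless of predicted class, best IoU first); each
#' match increments cell (predicted class, true class).  Unmatched ground
#' truths go to the background row, unmatched detections to the background
#' column.
#'
#' @param dets,gts as in [evaluate_detections()].
#' @param nc number of classes.
#' @param conf_thr,iou_thr thresholds in \[0, 1\].
#' @param normalize divide each true-class column by its sum.
#' @return `(nc+1) x (nc+1)` matrix; row/column `nc+1` is background.
#' @export
confusion_matrix_det <- function(dets, gts, nc, conf_thr = 0.25,
                                 iou_thr = 0.45, normalize = FALSE) {
  stopifnot(conf_thr >= 0, conf_thr <= 1, iou_thr >= 0, iou_thr <= 1)
  cm <- matrix(0, nc + 1, nc + 1)
  lab <- c(paste0("class", seq_len(nc) - 1), "background")
  dimnames(cm) <- list(predicted = lab, true = lab)
  dets <- dets[dets$confidence >= conf_thr, , drop = FALSE]
  cols <- c("x1", "y1", "x2", "y2")
  images <- unique(c(dets$image, gts$image))
  for (im in images) {
    di <- dets[dets$image == im, , drop = FALSE]
    di <- di[order(-di$confidence), , drop = FALSE]
    gi <- gts[gts$image == im, , drop = FALSE]
    used <- logical(nrow(gi))
    matched_d <- logical(nrow(di))
    if (nrow(di) > 0 && nrow(gi) > 0) {
      iou <- matrix(box_iou(as.matrix(di[, cols]), as.matrix(gi[, cols])),
                    nrow(di), nrow(gi))
      for (i in seq_len(nrow(di))) {
        cand <- which(!used & iou[i, ] >= iou_thr)
        if (length(cand) > 0) {
          j <- cand[which.max(iou[i, cand])]
          used[j] <- TRUE
          matched_d[i] <- TRUE
          cm[di$class_id[i] + 1, gi$class_id[j] + 1] <-
            cm[di$class_id[i] + 1, gi$class_id[j] + 1] + 1
        }
      }
    }
    if (nrow(di) > 0)
      for (i in which(!matched_d))
        cm[di$class_id[i] + 1, nc + 1] <- cm[di$class_id[i] + 1, nc + 1] + 1
    if (nrow(gi) > 0)
      for (j in which(!used))
        cm[nc + 1, gi$class_id[j] + 1] <- cm[nc + 1, gi$class_id[j] + 1] + 1
  }
  if (normalize) {
    cs <- colSums(cm)
    cs[cs == 0] <- 1
    cm <- sweep(cm, 2, cs, "/")
  }
  cm
}
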