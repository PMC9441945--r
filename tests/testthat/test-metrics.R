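test_that("IoU satisfies its defining identities", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1.0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0.0)
  # symmetry and translation invariance on random boxes
  set.seed(1)
  for (i in 1:20) {
    a <- sort(runif(2, 0, 10)); a <- c(a[1], runif(1), a[2], runif(1) + 2)
    a <- c(a[1], a[2], a[3], a[4])
    b <- c(runif(1, 0, 5), runif(1, 0, 5), runif(1, 6, 12), runif(1, 6, 12))
    expect_equal(box_iou(a, b), box_iou(b, a))
    t <- runif(2, -5, 5)
    expect_equal(box_iou(a + t[c(1, 2, 1, 2)], b + t[c(1, 2, 1, 2)]),
                 box_iou(a, b), tolerance = 1e-12)
  }
  expect_error(box_iou(c(0, 0, 0, 2), c(0, 0, 1, 1)), "degenerate")
})

test_that("NMS suppresses within classes only and is order-independent", {
  d <- det_df(class_id = c(0, 0), confidence = c(0.9, 0.8),
              x1 = c(0, 1), y1 = 0, x2 = c(10, 11), y2 = 10)  # IoU 0.8
  out <- nms_boxes(d, 0.45)
  expect_equal(nrow(out), 1)
  expect_equal(out$confidence, 0.9)
  # same boxes, different classes: both kept
  d2 <- d
  d2$class_id <- c(0, 1)
  expect_equal(nrow(nms_boxes(d2, 0.45)), 2)
  expect_equal(nrow(nms_boxes(d[0, ], 0.45)), 0)
  expect_error(nms_boxes(d, 1.5), "iou_thr")
  # permutation invariance for distinct confidences
  set.seed(7)
  big <- det_df(class_id = sample(0:1, 12, TRUE),
                confidence = sample(seq(0.3, 0.95, length.out = 12)),
                x1 = runif(12, 0, 50), y1 = runif(12, 0, 50))
  big$x2 <- big$x1 + runif(12, 5, 30)
  big$y2 <- big$y1 + runif(12, 5, 30)
  r1 <- nms_boxes(big, 0.5)
  r2 <- nms_boxes(big[sample(nrow(big)), ], 0.5)
  expect_equal(r1[order(r1$confidence), -1], r2[order(r2$confidence), -1],
               ignore_attr = TRUE)
})

test_that("evaluate reproduces hand-derived cases", {
  # perfect detections
  gt <- det_df(class_id = c(0, 1), x1 = c(0, 20), y1 = 0,
               x2 = c(10, 30), y2 = 10)
  det <- cbind(gt, confidence = 1)[, c("image", "class_id", "confidence",
                                       "x1", "y1", "x2", "y2")]
  ev <- evaluate_detections(det, gt, nc = 2)
  expect_equal(c(ev$precision, ev$recall, ev$ap50, ev$map), rep(1, 4))
  # one detection at IoU 0.6: AP50 = 1, mAP = 3/10
  gt1 <- det_df(class_id = 0, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  d1 <- det_df(class_id = 0, confidence = 1, x1 = 0, y1 = 0, x2 = 10, y2 = 6)
  ev1 <- evaluate_detections(d1, gt1, nc = 1)
  expect_equal(ev1$ap50, 1.0)
  expect_equal(ev1$map, 0.3)
  # TP = 9, FP = 1, FN = 0 at IoU 0.5 -> precision 0.9, recall 1.0
  gt9 <- det_df(class_id = 0, x1 = seq(0, 160, by = 20), y1 = 0,
                x2 = seq(10, 170, by = 20), y2 = 10)
  d9 <- rbind(cbind(gt9, confidence = 0.9),
              det_df(class_id = 0, confidence = 0.8, x1 = 500, y1 = 500,
                     x2 = 510, y2 = 510))
  ev9 <- evaluate_detections(d9[, c("image", "class_id", "confidence",
                                    "x1", "y1", "x2", "y2")], gt9, nc = 1)
  expect_equal(ev9$precision, 0.9)
  expect_equal(ev9$recall, 1.0)
  # classes with zero labels are excluded from the mean
  ev2 <- evaluate_detections(d1, gt1, nc = 3)
  expect_equal(ev2$map, ev1$map)
  expect_true(is.na(ev2$per_class$map[2]))
})

test_that("evaluation equals a naive reference implementation on small instances", {
  set.seed(42)
  for (case in 1:25) {
    inst <- random_eval_instance(nc = 3, n_images = 2)
    ev <- evaluate_detections(inst$dets, inst$gts, nc = 3)
    oe <- oracle_evaluate(inst$dets, inst$gts, nc = 3)
    for (f in c("precision", "recall", "ap50", "map"))
      expect_equal(ev[[f]], oe[[f]], info = sprintf("case %d %s", case, f))
  }
})

test_that("mAP is non-increasing in the IoU threshold", {
  set.seed(9)
  gt <- det_df(class_id = rep(0, 5), x1 = runif(5, 0, 80), y1 = runif(5, 0, 80))
  gt$x2 <- gt$x1 + runif(5, 10, 30)
  gt$y2 <- gt$y1 + runif(5, 10, 30)
  det <- gt
  det$confidence <- runif(5, 0.5, 1)
  det[, c("x1", "y1", "x2", "y2")] <-
    det[, c("x1", "y1", "x2", "y2")] + matrix(runif(20, -3, 3), 5)
  det <- det[, c("image", "class_id", "confidence", "x1", "y1", "x2", "y2")]
  thrs <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(thrs, function(t)
    evaluate_detections(det, gt, iou_thresholds = t, nc = 1)$map, numeric(1))
  expect_true(all(diff(aps) <= 1e-12))
})

test_that("confusion matrix books matches, misses and false alarms", {
  gt <- det_df(class_id = c(0, 1), x1 = c(0, 40), y1 = 0,
               x2 = c(10, 50), y2 = 10)
  # perfect -> identity on the class block
  det <- cbind(gt, confidence = 0.9)[, c("image", "class_id", "confidence",
                                         "x1", "y1", "x2", "y2")]
  cm <- confusion_matrix_det(det, gt, nc = 2)
  expect_equal(unname(cm[1:2, 1:2]), diag(2))
  # no detections -> all mass in the background row
  cm0 <- confusion_matrix_det(det[0, ], gt, nc = 2)
  expect_equal(unname(cm0[3, 1:2]), c(1, 1))
  expect_equal(sum(cm0[1:2, ]), 0)
  # one misclassified match -> single off-diagonal cell = 1 in its column
  det_mis <- det[1, ]
  det_mis$class_id <- 1
  cmn <- confusion_matrix_det(det_mis, gt[1, ], nc = 2, normalize = TRUE)
  expect_equal(unname(cmn[2, 1]), 1)
  # normalized true-class columns sum to 1
  cmn2 <- confusion_matrix_det(det, gt, nc = 2, normalize = TRUE)
  expect_equal(unname(colSums(cmn2)[1:2]), c(1, 1))
})
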