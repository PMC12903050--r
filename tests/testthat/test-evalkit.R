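test_that("iou matches hand values and the pixel-enumeration oracle", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1.0)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0.0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 50 / 150)
  expect_error(iou(c(0, 0, 0, 10), c(0, 0, 5, 5)), "degenerate")

  set.seed(42)
  a <- random_boxes(300); b <- random_boxes(300)
  for (i in 1:300) {
    v <- iou(a[i, ], b[i, ])
    expect_equal(v, iou(b[i, ], a[i, ]))  # symmetry
    expect_true(v >= 0 && v <= 1)
    o <- iou_pixel_oracle(as.numeric(a[i, 1:4]), as.numeric(b[i, 1:4]))
    expect_equal(v, o, tolerance = 1e-9)
  }
})

test_that("match_detections follows the greedy one-to-one protocol", {
  gt <- bounding_boxes(0, 0, 10, 10)
  p1 <- detection_set(bounding_boxes(0, 0, 10, 10, confidence = 0.95))
  r <- match_detections(p1, gt)
  expect_equal(c(r$TP, r$FP, r$FN), c(1L, 0L, 0L))

  # two predictions over one GT: one TP, one FP
  p2 <- detection_set(bounding_boxes(c(0, 1), c(0, 1), c(10, 11), c(10, 11),
                                     confidence = c(0.99, 0.95)))
  r2 <- match_detections(p2, gt)
  expect_equal(c(r2$TP, r2$FP, r2$FN), c(1L, 1L, 0L))
  expect_equal(r2$matches$pred, 1L)  # the higher-confidence one claimed it

  expect_error(match_detections(bounding_boxes(0, 0, 5, 5), gt),
               "confidences")
})

test_that("match report count identities hold on random instances", {
  set.seed(7)
  for (i in 1:200) {
    preds <- detection_set(random_boxes(sample(0:6, 1), confidence = TRUE))
    gts <- random_boxes(sample(0:6, 1))
    r <- match_detections(preds, gts)
    expect_equal(r$TP + r$FN, nrow(gts))
    expect_equal(r$TP + r$FP, nrow(preds))
    expect_true(!anyDuplicated(r$matches$gt))
    expect_true(!anyDuplicated(r$matches$pred))
    if (nrow(r$matches)) expect_true(all(r$matches$iou >= r$iou_threshold))
  }
})

test_that("precision_recall reproduces exact ratios and conventions", {
  mk <- function(tp, fp, fn) structure(list(TP = tp, FP = fp, FN = fn),
                                       class = "match_report")
  expect_equal(precision_recall(mk(9, 1, 0)), c(precision = 0.9, recall = 1.0))
  expect_equal(precision_recall(mk(0, 0, 5)), c(precision = 1.0, recall = 0.0))
  expect_equal(precision_recall(mk(48, 2, 2)),
               c(precision = 0.96, recall = 0.96))
  set.seed(3)
  for (i in 1:50) {
    tp <- sample(0:50, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    pr <- precision_recall(mk(tp, fp, fn))
    expect_identical(pr[["precision"]],
                     if (tp + fp == 0) 1.0 else tp / (tp + fp))
    expect_identical(pr[["recall"]],
                     if (tp + fn == 0) 1.0 else tp / (tp + fn))
  }
})

test_that("average_precision hits the closed-form extremes", {
  gts <- list(random_boxes(3), random_boxes(2))
  perfect <- lapply(gts, function(g) {
    g$confidence <- seq(0.99, 0.9, length.out = nrow(g))
    detection_set(g)
  })
  expect_equal(average_precision(perfect, gts)$ap, 1.0)

  # detector emitting only far-away false positives
  fps <- lapply(gts, function(g)
    detection_set(bounding_boxes(90, 90, 99, 99, confidence = 0.99)))
  off_gts <- list(bounding_boxes(0, 0, 10, 10), bounding_boxes(0, 0, 10, 10))
  expect_equal(average_precision(fps, off_gts)$ap, 0.0)

  expect_error(average_precision(perfect, list(bounding_boxes(),
                                               bounding_boxes())),
               "no ground-truth")
})

test_that("average_precision equals the exhaustive sweep oracle", {
  set.seed(12)
  for (i in 1:60) {
    n_img <- sample(1:3, 1)
    gts <- lapply(seq_len(n_img), function(k) random_boxes(sample(1:4, 1)))
    preds <- lapply(seq_len(n_img), function(k) {
      # half near-GT, half random, to get a mix of TPs and FPs
      g <- gts[[k]]
      near <- g[sample(nrow(g), sample(0:nrow(g), 1)), , drop = FALSE]
      if (nrow(near)) {
        near[, 1:4] <- near[, 1:4] + sample(-2:2, 4 * nrow(near), replace = TRUE)
        near <- near[near$x_max > near$x_min & near$y_max > near$y_min, ,
                     drop = FALSE]
      }
      extra <- random_boxes(sample(0:3, 1))
      all <- rbind(near, extra)
      all$confidence <- round(stats::runif(nrow(all)), 2)
      detection_set(all)
    })
    if (sum(vapply(preds, nrow, 1L)) == 0L) next
    expect_equal(average_precision(preds, gts)$ap,
                 ap_sweep_oracle(preds, gts), tolerance = 1e-12)
  }
})

test_that("average_precision is invariant to duplicate-confidence reordering", {
  set.seed(5)
  gts <- list(random_boxes(4))
  p <- random_boxes(6)
  p$confidence <- c(0.9, 0.9, 0.8, 0.8, 0.8, 0.7)
  ap1 <- average_precision(list(detection_set(p)), gts)$ap
  p_shuf <- p[sample(nrow(p)), , drop = FALSE]
  ap2 <- average_precision(list(detection_set(p_shuf)), gts)$ap
  expect_identical(ap1, ap2)
})

test_that("greedy matching is near-optimal against brute-force assignment", {
  set.seed(99)
  agree <- 0L; n_runs <- 300L
  for (i in seq_len(n_runs)) {
    preds <- detection_set(random_boxes(sample(1:6, 1), w = 40, h = 40,
                                        max_side = 25, confidence = TRUE))
    gts <- random_boxes(sample(1:6, 1), w = 40, h = 40, max_side = 25)
    g_tp <- match_detections(preds, gts)$TP
    o_tp <- optimal_tp_count(preds, gts)
    expect_lte(g_tp, o_tp)
    if (g_tp == o_tp) agree <- agree + 1L
  }
  expect_gte(agree / n_runs, 0.95)
})
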