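# Shared fixtures and independent oracles. Expensive fixtures (a trained
# detector) are built once per test run and memoized.

fixture_cache <- new.env(parent = emptyenv())

# A well-trained detector: 30 synthetic chambers spanning all layouts.
fixture_model <- function() {
  if (is.null(fixture_cache$model)) {
    train <- synth_dataset(30, seed = 21, n_cells_range = c(1L, 10L))
    fixture_cache$model <- train_detector(train, train_config(seed = 5))
  }
  fixture_cache$model
}

fixture_testset <- function() {
  if (is.null(fixture_cache$testset)) {
    fixture_cache$testset <- synth_dataset(20, seed = 999)
  }
  fixture_cache$testset
}

# Strip detection-set attributes, leaving only the box columns, so frames
# from different sources compare on content.
det_frame <- function(d) {
  out <- as.data.frame(d)[, c("x_min", "y_min", "x_max", "y_max", "label",
                              "confidence")]
  attr(out, "image_id") <- NULL
  attr(out, "model") <- NULL
  attr(out, "threshold") <- NULL
  rownames(out) <- NULL
  out
}

# Random integer-coordinate boxes inside a w x h canvas (min side 2).
random_boxes <- function(n, w = 100, h = 100, max_side = 30,
                         confidence = FALSE) {
  x0 <- sample(0:(w - 3), n, replace = TRUE)
  y0 <- sample(0:(h - 3), n, replace = TRUE)
  bw <- sample(2:max_side, n, replace = TRUE)
  bh <- sample(2:max_side, n, replace = TRUE)
  bounding_boxes(x0, y0, pmin(x0 + bw, w), pmin(y0 + bh, h),
                 confidence = if (confidence) round(stats::runif(n), 3) else NA_real_)
}

# Pixel-enumeration IoU oracle for integer-coordinate boxes: counts the
# integer pixels covered by each half-open rectangle.
iou_pixel_oracle <- function(a, b) {
  cover <- function(bx) {
    xs <- seq(bx[1], bx[3] - 1); ys <- seq(bx[2], bx[4] - 1)
    as.vector(outer(xs * 65536, ys, `+`))   # unique integer id per pixel
  }
  pa <- cover(as.numeric(a[1:4])); pb <- cover(as.numeric(b[1:4]))
  n_int <- length(intersect(pa, pb))
  n_int / (length(pa) + length(pb) - n_int)
}

# Brute-force maximum bipartite matching (augmenting paths) between
# predictions and ground truth over the IoU >= threshold admissibility
# graph: the optimal-assignment TP count the greedy matcher is compared to.
optimal_tp_count <- function(preds, gts, iou_threshold = 0.5) {
  np <- nrow(preds); ng <- nrow(gts)
  if (np == 0L || ng == 0L) return(0L)
  M <- matrix(FALSE, np, ng)
  for (i in seq_len(np)) {
    for (j in seq_len(ng)) {
      M[i, j] <- iou(preds[i, ], gts[j, ]) >= iou_threshold
    }
  }
  match_gt <- rep(0L, ng)
  try_augment <- function(i, seen) {
    for (j in which(M[i, ])) {
      if (!seen[j]) {
        seen[j] <- TRUE
        if (match_gt[j] == 0L || Recall(match_gt[j], seen)) {
          match_gt[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  tp <- 0L
  for (i in seq_len(np)) {
    if (try_augment(i, rep(FALSE, ng))) tp <- tp + 1L
  }
  tp
}

# Exhaustive confidence-sweep AP oracle: at every distinct confidence
# cutoff, match the retained predictions per image, pool TP/FP, and
# integrate the all-point-interpolated PR curve.
ap_sweep_oracle <- function(preds_per_image, gts_per_image,
                            iou_threshold = 0.5) {
  n_gt <- sum(vapply(gts_per_image, nrow, 1L))
  confs <- sort(unique(unlist(lapply(preds_per_image, function(p) p$confidence))),
                decreasing = TRUE)
  pts <- data.frame(recall = numeric(), precision = numeric())
  for (t in confs) {
    tp <- 0L; fp <- 0L
    for (k in seq_along(preds_per_image)) {
      kept <- preds_per_image[[k]][preds_per_image[[k]]$confidence >= t, ,
                                   drop = FALSE]
      r <- match_detections(kept, gts_per_image[[k]], iou_threshold)
      tp <- tp + r$TP; fp <- fp + r$FP
    }
    pts <- rbind(pts, data.frame(recall = tp / n_gt,
                                 precision = tp / max(tp + fp, 1L)))
  }
  pts <- pts[order(pts$recall), , drop = FALSE]
  env <- rev(cummax(rev(pts$precision)))
  sum(diff(c(0, pts$recall)) * env)
}

# Analytic equal-sigma crossing of two Gaussian densities with weights w1, w2.
gaussian_crossing <- function(w1, mu1, w2, mu2, sigma) {
  (mu1 + mu2) / 2 + sigma^2 * log(w1 / w2) / (mu2 - mu1)
}

# Flat synthetic background image (no chamber, no cells).
blank_image <- function(h = 100, w = 200, seed = 4) {
  set.seed(seed)
  img <- matrix(0.55, h, w) + matrix(stats::rnorm(h * w, 0, 0.02), h, w)
  pmin(pmax(img, 0), 1)
}

# Noiseless uniform disk on a flat background.
disk_image <- function(cx, cy, r, h = 100, w = 100, fg = 0.8, bg = 0.2) {
  xs <- outer(rep(1, h), (1:w) - 0.5)
  ys <- outer((1:h) - 0.5, rep(1, w))
  img <- matrix(bg, h, w)
  img[sqrt((xs - cx)^2 + (ys - cy)^2) <= r] <- fg
  img
}
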