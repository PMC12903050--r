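#' Intersection over union of two boxes
#'
#' `IoU = area(intersection) / area(union)` of two axis-aligned boxes in
#' continuous half-open coordinates. Symmetric; 0 for disjoint boxes, 1 for
#' identical boxes. The pipeline uses an IoU cutoff of 0.5 to call a
#' detection valid.
#'
#' @param a,b Single-row bounding-box data.frames, or numeric vectors
#'   `c(x_min, y_min, x_max, y_max)`.
#' @return IoU in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  a <- as_box_vec(a); b <- as_box_vec(b)
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2]) {
    stop("degenerate box", call. = FALSE)
  }
  ix <- min(a[3], b[3]) - max(a[1], b[1])
  iy <- min(a[4], b[4]) - max(a[2], b[2])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

as_box_vec <- function(b) {
  if (is.data.frame(b)) {
    as.numeric(c(b$x_min[1], b$y_min[1], b$x_max[1], b$y_max[1]))
  } else as.numeric(b[1:4])
}

# All-pairs IoU matrix: rows = boxes of `a`, cols = boxes of `b`. Vectorized.
iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(matrix(0, na, nb))
  ix <- outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax)
  iy <- outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax)
  inter <- pmax(ix, 0) * pmax(iy, 0)
  union <- outer(box_area(a), box_area(b), `+`) - inter
  inter / union
}

#' Match predictions to ground truth at an IoU cutoff
#'
#' Greedy, confidence-ordered one-to-one matching (the usual VOC protocol):
#' predictions are visited in descending confidence (ties broken by `x_min`,
#' then `y_min`); each claims the not-yet-matched ground-truth box of
#' highest IoU if that IoU reaches `iou_threshold` (a true positive, TP),
#' otherwise it is a false positive (FP). Ground-truth boxes left unclaimed
#' are false negatives (FN). IoU ties between ground-truth boxes are broken
#' by lower index.
#'
#' @param preds Detections (data.frame with confidences).
#' @param gts Ground-truth bounding-box data.frame.
#' @param iou_threshold IoU cutoff, default 0.5.
#' @return An object of class `match_report`: list with counts `TP`, `FP`,
#'   `FN`, a `matches` data.frame (`pred`, `gt`, `iou`; 1-based indices into
#'   the confidence-sorted predictions and `gts`), `pred_order` (the sort
#'   order applied to `preds`), and the thresholds used.
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  stopifnot_scalar(iou_threshold, "iou_threshold", 0, 1)
  validate_boxes(preds); validate_boxes(gts)
  if (nrow(preds) > 0L && any(is.na(preds$confidence))) {
    stop("predictions must carry confidences", call. = FALSE)
  }
  o <- order(-preds$confidence, preds$x_min, preds$y_min)
  p <- preds[o, , drop = FALSE]
  np <- nrow(p); ng <- nrow(gts)
  M <- iou_matrix(p, gts)
  gt_taken <- rep(FALSE, ng)
  matches <- data.frame(pred = integer(), gt = integer(), iou = numeric())
  for (i in seq_len(np)) {
    if (ng == 0L) break
    ious <- M[i, ]
    ious[gt_taken] <- -1
    j <- which.max(ious)          # ties -> lowest index, as documented
    if (length(j) == 1L && ious[j] >= iou_threshold) {
      gt_taken[j] <- TRUE
      matches <- rbind(matches, data.frame(pred = i, gt = j, iou = ious[j]))
    }
  }
  tp <- nrow(matches)
  structure(list(
    TP = tp, FP = np - tp, FN = ng - tp,
    matches = matches, pred_order = o,
    iou_threshold = iou_threshold,
    confidence_threshold = attr(preds, "threshold") %||% NA_real_
  ), class = "match_report")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> TP=%d FP=%d FN=%d (IoU >= %.2f)\n",
              x$TP, x$FP, x$FN, x$iou_threshold))
  invisible(x)
}

#' Precision and recall from a match report
#'
#' `Precision = TP / (TP + FP)` and `Recall = TP / (TP + FN)`. By
#' convention, precision is 1 when no predictions were made and recall is 1
#' when there is no ground truth (nothing to miss).
#'
#' @param report A `match_report`.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(report) {
  p <- if (report$TP + report$FP == 0L) 1.0 else report$TP / (report$TP + report$FP)
  r <- if (report$TP + report$FN == 0L) 1.0 else report$TP / (report$TP + report$FN)
  c(precision = p, recall = r)
}

#' Average precision over a set of images
#'
#' All-point-interpolated area under the precision-recall curve obtained by
#' sweeping the confidence threshold across every distinct predicted
#' confidence, pooling TP/FP/FN over images, with per-image greedy matching
#' as in [match_detections()]. Because greedy confidence-ordered matching is
#' prefix-consistent (adding lower-confidence predictions never alters
#' earlier matches), the sweep is computed incrementally.
#'
#' Also reports precision and recall at a fixed confidence cutoff (default
#' 0.9), since detector quality in this pipeline is often quoted at that
#' operating point.
#'
#' @param preds_per_image List of detection sets, one per image.
#' @param gts_per_image List of ground-truth box data.frames, same length.
#' @param iou_threshold IoU cutoff, default 0.5.
#' @param conf_threshold Operating point for the at-threshold precision.
#' @return List with `ap`, `precision_at`, `recall_at`, `conf_threshold`,
#'   and the pooled PR `curve` data.frame.
#' @export
average_precision <- function(preds_per_image, gts_per_image,
                              iou_threshold = 0.5, conf_threshold = 0.9) {
  if (length(preds_per_image) != length(gts_per_image)) {
    stop("preds and gts lists must have equal length", call. = FALSE)
  }
  n_gt <- sum(vapply(gts_per_image, nrow, 1L))
  if (n_gt == 0L) stop("no ground-truth boxes: AP undefined", call. = FALSE)
  rows <- NULL
  for (k in seq_along(preds_per_image)) {
    p <- preds_per_image[[k]]
    g <- gts_per_image[[k]]
    rep_k <- match_detections(p, g, iou_threshold)
    np <- nrow(p)
    if (np == 0L) next
    o <- rep_k$pred_order
    is_tp <- rep(FALSE, np)
    if (nrow(rep_k$matches) > 0L) is_tp[rep_k$matches$pred] <- TRUE
    conf_sorted <- p$confidence[o]
    rows <- rbind(rows, data.frame(conf = conf_sorted, tp = is_tp,
                                   x = p$x_min[o], y = p$y_min[o]))
  }
  if (is.null(rows) || nrow(rows) == 0L) {
    return(list(ap = 0, precision_at = 1.0, recall_at = 0,
                conf_threshold = conf_threshold,
                curve = data.frame(recall = numeric(), precision = numeric(),
                                   conf = numeric())))
  }
  o <- order(-rows$conf, rows$x, rows$y)
  rows <- rows[o, , drop = FALSE]
  tp_cum <- cumsum(rows$tp)
  fp_cum <- cumsum(!rows$tp)
  rec <- tp_cum / n_gt
  prec <- tp_cum / (tp_cum + fp_cum)
  # evaluate at each distinct confidence (last entry of each tie group)
  keep <- !duplicated(rows$conf, fromLast = TRUE)
  rec_k <- rec[keep]; prec_k <- prec[keep]; conf_k <- rows$conf[keep]
  # all-point interpolation: precision envelope from the right
  env <- rev(cummax(rev(prec_k)))
  ap <- sum(diff(c(0, rec_k)) * env)
  at <- rows$conf >= conf_threshold
  tp_at <- sum(rows$tp[at]); fp_at <- sum(!rows$tp[at])
  list(
    ap = ap,
    precision_at = if (tp_at + fp_at == 0L) 1.0 else tp_at / (tp_at + fp_at),
    recall_at = tp_at / n_gt,
    conf_threshold = conf_threshold,
    curve = data.frame(recall = rec_k, precision = prec_k, conf = conf_k)
  )
}
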