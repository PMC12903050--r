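#' Construct a bounding-box table
#'
#' Boxes are axis-aligned rectangles in 0-based, half-open pixel coordinates:
#' a box covers pixel columns `[x_min, x_max)` and rows `[y_min, y_max)`, so
#' its area is `(x_max - x_min) * (y_max - y_min)` with no off-by-one
#' ambiguity. Ground-truth boxes carry `confidence = NA`; detector output
#' carries a confidence in `[0, 1]`.
#'
#' @param x_min,y_min,x_max,y_max Numeric vectors of box edges (pixels).
#' @param label Character vector of class labels (recycled).
#' @param confidence Numeric vector of confidences in `[0, 1]`, or `NA` for
#'   ground truth.
#' @return A `data.frame` with columns `x_min, y_min, x_max, y_max, label,
#'   confidence`.
#' @examples
#' bounding_boxes(0, 0, 10, 10)
#' @export
bounding_boxes <- function(x_min = numeric(), y_min = numeric(),
                           x_max = numeric(), y_max = numeric(),
                           label = "cell", confidence = NA_real_) {
  n <- length(x_min)
  df <- data.frame(
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max),
    label = rep_len(as.character(label), n),
    confidence = rep_len(as.numeric(confidence), n),
    stringsAsFactors = FALSE
  )
  validate_boxes(df)
  df
}

#' Validate a bounding-box table
#'
#' Checks the box invariants: `x_max > x_min`, `y_max > y_min`, and
#' confidences (when present) in `[0, 1]`.
#'
#' @param boxes A bounding-box `data.frame` (see [bounding_boxes()]).
#' @return The input, invisibly; errors on violation.
#' @export
validate_boxes <- function(boxes) {
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (!all(need %in% names(boxes))) {
    stop("boxes must have columns x_min, y_min, x_max, y_max", call. = FALSE)
  }
  if (nrow(boxes) > 0L) {
    if (any(!is.finite(boxes$x_min)) || any(!is.finite(boxes$x_max)) ||
        any(!is.finite(boxes$y_min)) || any(!is.finite(boxes$y_max))) {
      stop("box coordinates must be finite", call. = FALSE)
    }
    if (any(boxes$x_max <= boxes$x_min) || any(boxes$y_max <= boxes$y_min)) {
      stop("degenerate box: requires x_max > x_min and y_max > y_min",
           call. = FALSE)
    }
    if ("confidence" %in% names(boxes)) {
      cf <- boxes$confidence
      bad <- !is.na(cf) & (cf < 0 | cf > 1)
      if (any(bad)) stop("confidence must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(boxes)
}

#' Areas of boxes
#' @param boxes A bounding-box `data.frame`.
#' @return Numeric vector of areas in square pixels.
#' @export
box_area <- function(boxes) {
  (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
}

#' Construct a detection set
#'
#' A detection set is a bounding-box table tagged with the image it belongs
#' to and the model that produced it. Boxes are stored sorted by descending
#' confidence (ties broken by `x_min`, then `y_min`, deterministically).
#'
#' @param boxes Bounding-box `data.frame` with non-missing confidences.
#' @param image_id Character scalar identifying the image.
#' @param model Character scalar identifying the producing model.
#' @param threshold Confidence threshold already applied, if any.
#' @return An object of class `chip_detections` (a data.frame with
#'   attributes `image_id`, `model`, `threshold`).
#' @export
detection_set <- function(boxes, image_id = "image", model = "unknown",
                          threshold = NA_real_) {
  validate_boxes(boxes)
  if (nrow(boxes) > 0L && any(is.na(boxes$confidence))) {
    stop("detections must carry confidences", call. = FALSE)
  }
  o <- order(-boxes$confidence, boxes$x_min, boxes$y_min)
  boxes <- boxes[o, , drop = FALSE]
  rownames(boxes) <- NULL
  structure(boxes,
            image_id = image_id, model = model, threshold = threshold,
            class = c("chip_detections", "data.frame"))
}

#' @export
print.chip_detections <- function(x, ...) {
  cat(sprintf("<chip_detections> image=%s model=%s n=%d\n",
              attr(x, "image_id"), attr(x, "model"), nrow(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Filter detections by confidence
#'
#' Keeps boxes with `confidence >= threshold`, preserving order. Raising the
#' threshold can never increase the number of boxes kept.
#'
#' @param det A `chip_detections` object (or bounding-box data.frame with
#'   confidences).
#' @param threshold Confidence cutoff in `[0, 1]`; the pipeline default is
#'   0.9.
#' @return The filtered detection set, with its `threshold` attribute set.
#' @export
filter_by_confidence <- function(det, threshold = 0.9) {
  stopifnot_scalar(threshold, "threshold", 0, 1)
  keep <- !is.na(det$confidence) & det$confidence >= threshold
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "image_id") <- attr(det, "image_id")
  attr(out, "model") <- attr(det, "model")
  attr(out, "threshold") <- threshold
  class(out) <- class(det)
  out
}

# Clip boxes to [0, w) x [0, h), dropping boxes that vanish entirely.
clip_boxes <- function(boxes, width, height) {
  if (nrow(boxes) == 0L) return(boxes)
  boxes$x_min <- pmax(boxes$x_min, 0)
  boxes$y_min <- pmax(boxes$y_min, 0)
  boxes$x_max <- pmin(boxes$x_max, width)
  boxes$y_max <- pmin(boxes$y_max, height)
  keep <- boxes$x_max > boxes$x_min & boxes$y_max > boxes$y_min
  out <- boxes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
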