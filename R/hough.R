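#' Configuration for the circular-Hough baseline
#'
#' The conventional circle-detection baseline the trained detector is
#' compared against. Circles with radius outside
#' `[radius_min_px, radius_max_px]` are discarded (defaults 5 and 100 px).
#'
#' @param radius_min_px,radius_max_px Radius band in pixels,
#'   `0 < radius_min_px < radius_max_px`.
#' @param radius_step_px Radius grid step of the accumulator.
#' @param sensitivity Accumulator peak acceptance threshold as a fraction of
#'   the theoretical full-ring vote; lower accepts weaker circles.
#' @param suppress_factor Peaks whose center lies within
#'   `suppress_factor * r` of an already accepted stronger peak are dropped.
#'   Set to 0 to disable duplicate suppression and reproduce the classic
#'   multiple-circles-per-cell failure mode.
#' @param max_detections Cap on emitted circles per image.
#' @return An object of class `hough_config`.
#' @export
hough_config <- function(radius_min_px = 5, radius_max_px = 100,
                         radius_step_px = 1, sensitivity = 0.33,
                         suppress_factor = 0.5, max_detections = 50L) {
  if (radius_min_px <= 0 || radius_max_px <= radius_min_px) {
    stop("need 0 < radius_min_px < radius_max_px", call. = FALSE)
  }
  if (radius_step_px <= 0) stop("radius_step_px must be > 0", call. = FALSE)
  stopifnot_scalar(sensitivity, "sensitivity", 0, 1)
  structure(list(radius_min_px = radius_min_px, radius_max_px = radius_max_px,
                 radius_step_px = radius_step_px, sensitivity = sensitivity,
                 suppress_factor = suppress_factor,
                 max_detections = as.integer(max_detections)),
            class = "hough_config")
}

#' Detect circles by circular Hough transform
#'
#' Textbook pipeline: Sobel gradient magnitude, Otsu-thresholded edge map,
#' 3-D `(cx, cy, r)` accumulator built by voting each edge pixel onto
#' circles of every candidate radius (implemented as FFT correlation of the
#' edge map with ring kernels), per-radius vote normalization by ring
#' circumference, non-maximum suppression over a radius-scaled neighborhood,
#' and a radius band filter. Each accepted circle `(cx, cy, r)` is emitted
#' as the box `(cx - r, cy - r, cx + r, cy + r)` with the normalized
#' accumulator peak (fraction of the ring supported by edges, capped at 1)
#' as its confidence.
#'
#' @param image Single-channel numeric matrix.
#' @param config A [hough_config()].
#' @param image_id Identifier recorded on the output.
#' @return A `chip_detections` object.
#' @export
detect_circles <- function(image, config = hough_config(), image_id = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a single-channel numeric matrix", call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  img <- norm_image(image)
  g <- sobel_magnitude(img)
  if (max(g) == 0) {
    return(detection_set(bounding_boxes(), image_id = image_id, model = "hough"))
  }
  edges <- g > otsu_threshold(as.vector(g))
  edge_m <- matrix(as.numeric(edges), h, w)
  # the ring kernel spans 2r + 3 pixels and must fit inside the image
  r_cap <- floor((min(h, w) - 3) / 2)
  if (r_cap < config$radius_min_px) {
    return(detection_set(bounding_boxes(), image_id = image_id, model = "hough"))
  }
  radii <- seq(config$radius_min_px, min(config$radius_max_px, r_cap),
               by = config$radius_step_px)
  if (length(radii) == 0L) {
    return(detection_set(bounding_boxes(), image_id = image_id, model = "hough"))
  }
  cands <- NULL
  for (r in radii) {
    kern <- ring_kernel(r)          # normalized to sum 1 -> vote fraction
    acc <- xcorr_fft(edge_m, embed_kernel(kern, h, w))
    pk <- local_maxima(acc, k = 2L, thr = config$sensitivity)
    if (nrow(pk) > 0L) {
      cands <- rbind(cands, data.frame(
        cx = pk$col - 0.5, cy = pk$row - 0.5, r = r, score = pk$value))
    }
  }
  if (is.null(cands) || nrow(cands) == 0L) {
    return(detection_set(bounding_boxes(), image_id = image_id, model = "hough"))
  }
  cands <- cands[order(-cands$score, cands$cx, cands$cy), , drop = FALSE]
  keep <- NULL
  for (i in seq_len(nrow(cands))) {
    if (is.null(keep)) { keep <- cands[i, , drop = FALSE]; next }
    d <- sqrt((keep$cx - cands$cx[i])^2 + (keep$cy - cands$cy[i])^2)
    if (all(d >= config$suppress_factor * pmax(keep$r, cands$r[i]))) {
      keep <- rbind(keep, cands[i, , drop = FALSE])
    }
    if (nrow(keep) >= config$max_detections) break
  }
  boxes <- data.frame(
    x_min = keep$cx - keep$r, y_min = keep$cy - keep$r,
    x_max = keep$cx + keep$r, y_max = keep$cy + keep$r,
    label = "cell", confidence = pmin(keep$score, 1))
  boxes <- clip_boxes(boxes, w, h)
  detection_set(boxes, image_id = image_id, model = "hough")
}
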