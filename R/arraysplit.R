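#' Crop a whole-array image into individual-chamber images
#'
#' Given chamber detections on a whole-array image, drops oversized
#' inferences (area greater than `oversize_factor` times the median detected
#' area) and inferences on the edges (any box side within `edge_margin_px`
#' of the image border — chambers partially out of the field of view), then
#' returns one padded crop per surviving chamber together with its global
#' offset, so cell boxes detected inside a crop can be mapped back to array
#' coordinates with [map_to_array_coords()].
#'
#' @param image Whole-array numeric matrix.
#' @param chamber_dets Chamber detections (`chip_detections` or bounding-box
#'   data.frame).
#' @param oversize_factor Area multiple of the median above which a box is
#'   dropped (default 1.5).
#' @param edge_margin_px Border proximity (px) at which a box counts as
#'   edge-touching (default 2).
#' @param pad_px Padding added around each crop, clipped to image bounds.
#' @return A list of `list(crop, offset = c(x, y), box)`; empty (with a
#'   warning) when there are no chamber detections.
#' @export
split_array <- function(image, chamber_dets, oversize_factor = 1.5,
                        edge_margin_px = 2L, pad_px = 4L) {
  h <- nrow(image); w <- ncol(image)
  if (nrow(chamber_dets) == 0L) {
    warning("no chamber detections; returning empty crop list")
    return(list())
  }
  validate_boxes(chamber_dets)
  areas <- box_area(chamber_dets)
  med <- stats::median(areas)
  oversized <- areas > oversize_factor * med
  on_edge <- chamber_dets$x_min < edge_margin_px |
    chamber_dets$y_min < edge_margin_px |
    chamber_dets$x_max > w - edge_margin_px |
    chamber_dets$y_max > h - edge_margin_px
  keep <- which(!oversized & !on_edge)
  lapply(keep, function(i) {
    b <- chamber_dets[i, ]
    x0 <- max(0, floor(b$x_min) - pad_px); y0 <- max(0, floor(b$y_min) - pad_px)
    x1 <- min(w, ceiling(b$x_max) + pad_px); y1 <- min(h, ceiling(b$y_max) + pad_px)
    list(crop = image[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE],
         offset = c(x = x0, y = y0),
         box = b)
  })
}

#' Translate a box from crop to array coordinates
#'
#' Pure translation by the crop's offset; `map_to_array_coords(b, offset)`
#' and `map_to_crop_coords(b, offset)` are exact inverses.
#'
#' @param box Bounding-box data.frame (any number of rows).
#' @param offset `c(x, y)` offset of the crop within the array image.
#' @return The translated boxes.
#' @export
map_to_array_coords <- function(box, offset) {
  box$x_min <- box$x_min + offset[[1]]
  box$x_max <- box$x_max + offset[[1]]
  box$y_min <- box$y_min + offset[[2]]
  box$y_max <- box$y_max + offset[[2]]
  box
}

#' @rdname map_to_array_coords
#' @export
map_to_crop_coords <- function(box, offset) {
  map_to_array_coords(box, -c(offset[[1]], offset[[2]]))
}
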