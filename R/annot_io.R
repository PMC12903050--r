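#' Read Pascal-VOC XML annotations
#'
#' Parses one VOC annotation file. VOC stores 1-based *inclusive* pixel
#' coordinates; they are converted to this package's 0-based half-open
#' convention (`x_min <- xmin - 1`, `x_max <- xmax`). Labels are preserved
#' verbatim.
#'
#' @param xml_path Path to a VOC XML file.
#' @return A list with `image_ref` (the `<filename>` element), `size`
#'   (`c(height, width)`), and `boxes` (bounding-box data.frame).
#' @export
read_voc <- function(xml_path) {
  if (!file.exists(xml_path)) {
    stop(sprintf("annotation file not found: %s", xml_path), call. = FALSE)
  }
  doc <- tryCatch(xml2::read_xml(xml_path), error = function(e) {
    stop(sprintf("malformed VOC XML in %s: %s", xml_path, conditionMessage(e)),
         call. = FALSE)
  })
  size_node <- xml2::xml_find_first(doc, "./size")
  if (inherits(size_node, "xml_missing")) {
    stop(sprintf("VOC XML %s: missing <size> element", xml_path), call. = FALSE)
  }
  width <- as.numeric(xml2::xml_text(xml2::xml_find_first(size_node, "./width")))
  height <- as.numeric(xml2::xml_text(xml2::xml_find_first(size_node, "./height")))
  if (!is.finite(width) || !is.finite(height)) {
    stop(sprintf("VOC XML %s: <size> lacks numeric width/height", xml_path),
         call. = FALSE)
  }
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  objs <- xml2::xml_find_all(doc, "./object")
  get1 <- function(node, xp) {
    n <- xml2::xml_find_first(node, xp)
    if (inherits(n, "xml_missing")) {
      stop(sprintf("VOC XML %s: object missing element %s", xml_path, xp),
           call. = FALSE)
    }
    xml2::xml_text(n)
  }
  boxes <- bounding_boxes()
  for (obj in objs) {
    lab <- get1(obj, "./name")
    xmin <- as.numeric(get1(obj, "./bndbox/xmin"))
    ymin <- as.numeric(get1(obj, "./bndbox/ymin"))
    xmax <- as.numeric(get1(obj, "./bndbox/xmax"))
    ymax <- as.numeric(get1(obj, "./bndbox/ymax"))
    if (xmax <= xmin || ymax <= ymin) {
      stop(sprintf("VOC XML %s: degenerate <bndbox> (%g,%g,%g,%g)",
                   xml_path, xmin, ymin, xmax, ymax), call. = FALSE)
    }
    if (xmin < 1 || ymin < 1 || xmax > width || ymax > height) {
      stop(sprintf(
        "VOC XML %s: <bndbox> (%g,%g,%g,%g) outside declared %gx%g image",
        xml_path, xmin, ymin, xmax, ymax, width, height), call. = FALSE)
    }
    boxes <- rbind(boxes, data.frame(
      x_min = xmin - 1, y_min = ymin - 1, x_max = xmax, y_max = ymax,
      label = lab, confidence = NA_real_, stringsAsFactors = FALSE))
  }
  rownames(boxes) <- NULL
  validate_boxes(boxes)
  list(image_ref = fname, size = c(height, width), boxes = boxes)
}

#' Write Pascal-VOC XML annotations
#'
#' Inverse of [read_voc()]: internal 0-based half-open coordinates are
#' converted back to VOC's 1-based inclusive convention. Non-integer
#' coordinates are rounded half-up. Element order is deterministic, so
#' write -> read -> write is byte-stable.
#'
#' @param image_ref Image file name to record.
#' @param boxes Bounding-box data.frame.
#' @param size `c(height, width)` of the image in pixels.
#' @param xml_path Output path.
#' @return `xml_path`, invisibly.
#' @export
write_voc <- function(image_ref, boxes, size, xml_path) {
  validate_boxes(boxes)
  round_half_up <- function(x) floor(x + 0.5)
  lines <- c(
    "<annotation>",
    sprintf("  <filename>%s</filename>", image_ref),
    "  <size>",
    sprintf("    <width>%d</width>", as.integer(size[2])),
    sprintf("    <height>%d</height>", as.integer(size[1])),
    "    <depth>1</depth>",
    "  </size>"
  )
  for (i in seq_len(nrow(boxes))) {
    lines <- c(lines,
      "  <object>",
      sprintf("    <name>%s</name>", boxes$label[i]),
      "    <bndbox>",
      sprintf("      <xmin>%d</xmin>", as.integer(round_half_up(boxes$x_min[i] + 1))),
      sprintf("      <ymin>%d</ymin>", as.integer(round_half_up(boxes$y_min[i] + 1))),
      sprintf("      <xmax>%d</xmax>", as.integer(round_half_up(boxes$x_max[i]))),
      sprintf("      <ymax>%d</ymax>", as.integer(round_half_up(boxes$y_max[i]))),
      "    </bndbox>",
      "  </object>")
  }
  lines <- c(lines, "</annotation>")
  writeLines(lines, xml_path)
  invisible(xml_path)
}

#' Write detector inferences to CSV
#'
#' One row per box, columns exactly `image_id, x_min, y_min, x_max, y_max,
#' label, confidence`, boxes of each image ordered by descending confidence.
#'
#' @param detections A `chip_detections` object or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_inferences_csv <- function(detections, path) {
  if (inherits(detections, "chip_detections")) detections <- list(detections)
  rows <- lapply(detections, function(d) {
    df <- as.data.frame(d)
    if (nrow(df) == 0L) return(NULL)
    o <- order(-df$confidence, df$x_min, df$y_min)
    df <- df[o, , drop = FALSE]
    cbind(image_id = attr(d, "image_id"),
          df[, c("x_min", "y_min", "x_max", "y_max", "label", "confidence")])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(image_id = character(), x_min = numeric(),
                      y_min = numeric(), x_max = numeric(), y_max = numeric(),
                      label = character(), confidence = numeric())
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read detector inferences from CSV
#'
#' Inverse of [write_inferences_csv()]; returns one `chip_detections` per
#' distinct `image_id`, in file order.
#'
#' @param path CSV path.
#' @return Named list of `chip_detections`.
#' @export
read_inferences_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "x_min", "y_min", "x_max", "y_max", "label", "confidence")
  if (!identical(names(df), need)) {
    stop(sprintf("inference CSV %s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  ids <- unique(df$image_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$image_id == id, -1, drop = FALSE]
    rownames(sub) <- NULL
    detection_set(sub, image_id = id)
  })
  names(out) <- ids
  out
}

#' Read COCO-JSON annotations (read-only interoperability)
#'
#' Imports a COCO object-detection JSON. COCO boxes are
#' `[x, y, width, height]` in 0-based pixel coordinates, which map directly
#' onto the internal half-open convention.
#'
#' @param path Path to a COCO JSON file.
#' @return Named list (by image file name) of bounding-box data.frames.
#' @export
read_coco <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(j$images) || is.null(j$annotations)) {
    stop(sprintf("COCO JSON %s: missing images/annotations", path), call. = FALSE)
  }
  cats <- if (!is.null(j$categories)) {
    stats::setNames(j$categories$name, j$categories$id)
  } else c()
  imgs <- stats::setNames(j$images$file_name, j$images$id)
  ann <- j$annotations
  bb <- do.call(rbind, ann$bbox)
  out <- lapply(names(imgs), function(iid) {
    sel <- ann$image_id == as.numeric(iid)
    if (!any(sel)) return(bounding_boxes())
    b <- bb[sel, , drop = FALSE]
    labs <- if (length(cats)) unname(cats[as.character(ann$category_id[sel])]) else "cell"
    bounding_boxes(b[, 1], b[, 2], b[, 1] + b[, 3], b[, 2] + b[, 4],
                   label = labs)
  })
  stats::setNames(out, unname(imgs))
}

#' Write an image as ASCII PGM (NetPBM P2)
#'
#' The pipeline's portable image format: plain-text portable graymap with a
#' 16-bit value range. Intensities in `[0, 1]` are scaled to `[0, maxval]`.
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param path Output path (conventionally `.pgm`).
#' @param maxval Maximum gray value (default 65535, i.e. 16-bit).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 65535L) {
  if (any(img < 0 | img > 1)) stop("image values must lie in [0, 1]", call. = FALSE)
  v <- round(t(img) * maxval)   # PGM is row-major, width fastest
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)),
               sprintf("%d", maxval)), con)
  writeLines(paste(format(as.integer(v)), collapse = "\n"), con)
  invisible(path)
}

#' Read a PGM image (P2 or P5)
#'
#' @param path PGM file path.
#' @return Numeric matrix with values scaled to `[0, 1]`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!magic %in% c("P2", "P5")) {
    stop(sprintf("%s: not a PGM file (magic %s)", path, magic), call. = FALSE)
  }
  header <- numeric(0)
  while (length(header) < 3L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*$", "", line)
    header <- c(header, as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  }
  w <- header[1]; h <- header[2]; maxval <- header[3]
  if (magic == "P2") {
    vals <- scan(con, what = numeric(), n = w * h, quiet = TRUE)
  } else {
    bytes <- if (maxval > 255) 2L else 1L
    raw <- readBin(con, "integer", n = w * h, size = bytes, signed = FALSE,
                   endian = "big")
    vals <- as.numeric(raw)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}
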