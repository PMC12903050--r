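#' Scene specification for synthetic chamber images
#'
#' Describes one synthetic bright-field scene of a microfluidic trap chamber:
#' the chamber layout, how many round suspension cells it holds, their size,
#' the visibility of the channel-wall contour (the PDMS-water refractive
#' index mismatch makes walls highly visible in bright-field), a defocus
#' proxy, and the per-image intensity relative standard deviation (RSD) to
#' reach. Real training images in this regime have per-image RSDs between
#' 15% and 27% and chambers holding 1 to 15 cells.
#'
#' The nominal pixel scale is 0.65 um/px (10x objective), so a ~15 um
#' lymphoblast is ~23 px across and a ~10 um T cell is ~15 px; 20x scenes
#' are emulated by doubling `cell_diameter_px`.
#'
#' @param image_size `c(height, width)` in pixels. Default `c(100, 200)`,
#'   the size of an individual-chamber crop.
#' @param chamber_type Integer 1..4 selecting one of four layouts that
#'   differ in chamber size and number of outlet channels (1-3).
#' @param n_cells Number of cells to place, in `[1, 15]`.
#' @param cell_diameter_px `c(mean, sd)` of cell diameter in pixels.
#' @param wall_contrast Relative brightness amplitude of the channel-wall
#'   double-edge contour, in `[0, 0.5]`.
#' @param blur_sigma_px Gaussian blur sigma (defocus proxy), `>= 0`.
#' @param target_rsd Target relative standard deviation of pixel
#'   intensities, in `[0.10, 0.35]`.
#' @param seed Integer RNG seed; identical specs give bit-identical scenes.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(100L, 200L),
                       chamber_type = 1L,
                       n_cells = 5L,
                       cell_diameter_px = c(23, 2),
                       wall_contrast = 0.35,
                       blur_sigma_px = 1.0,
                       target_rsd = 0.20,
                       seed = 1L) {
  if (length(image_size) != 2L || any(image_size < 32)) {
    stop("image_size must be c(height, width) with both >= 32", call. = FALSE)
  }
  if (!chamber_type %in% 1:4) stop("chamber_type must be 1..4", call. = FALSE)
  stopifnot_scalar(n_cells, "n_cells", 1, 15)
  if (n_cells != round(n_cells)) stop("n_cells must be an integer", call. = FALSE)
  if (length(cell_diameter_px) != 2L || cell_diameter_px[1] < 4 ||
      cell_diameter_px[2] < 0) {
    stop("cell_diameter_px must be c(mean >= 4, sd >= 0)", call. = FALSE)
  }
  stopifnot_scalar(wall_contrast, "wall_contrast", 0, 0.5)
  stopifnot_scalar(blur_sigma_px, "blur_sigma_px", 0, Inf)
  stopifnot_scalar(target_rsd, "target_rsd", 0.10, 0.35)
  structure(list(
    image_size = as.integer(image_size), chamber_type = as.integer(chamber_type),
    n_cells = as.integer(n_cells), cell_diameter_px = as.numeric(cell_diameter_px),
    wall_contrast = as.numeric(wall_contrast),
    blur_sigma_px = as.numeric(blur_sigma_px),
    target_rsd = as.numeric(target_rsd), seed = as.integer(seed)
  ), class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> %dx%d px, chamber type %d, %d cells (d=%.1f+-%.1f px), rsd=%.2f, blur=%.1f, seed=%d\n",
    x$image_size[1], x$image_size[2], x$chamber_type, x$n_cells,
    x$cell_diameter_px[1], x$cell_diameter_px[2], x$target_rsd,
    x$blur_sigma_px, x$seed))
  invisible(x)
}

# Chamber layout geometry: wall inset (px, scaled to image) and outlet count.
chamber_layout <- function(type, h, w) {
  base <- min(h, w)
  switch(type,
    `1` = list(inset_x = round(0.05 * w) + 3L, inset_y = round(0.06 * base) + 3L, n_outlets = 1L),
    `2` = list(inset_x = round(0.07 * w) + 3L, inset_y = round(0.08 * base) + 3L, n_outlets = 2L),
    `3` = list(inset_x = round(0.10 * w) + 3L, inset_y = round(0.12 * base) + 3L, n_outlets = 3L),
    `4` = list(inset_x = round(0.14 * w) + 3L, inset_y = round(0.16 * base) + 3L, n_outlets = 2L)
  )
}

# Draw the chamber wall double-edge contour (bright line flanked by a dark
# line, as the refractive-index mismatch renders it) onto `img` in place.
# Returns the image plus the interior rectangle (continuous coords).
draw_chamber <- function(img, layout, wall_contrast) {
  h <- nrow(img); w <- ncol(img)
  x0 <- layout$inset_x; x1 <- w - layout$inset_x
  y0 <- layout$inset_y; y1 <- h - layout$inset_y
  bg <- 0.55
  bright <- clamp01(bg + wall_contrast)
  dark <- clamp01(bg - wall_contrast * 0.85)
  rows_in <- (y0 + 1L):y1
  cols_in <- (x0 + 1L):x1
  # dark outer band (2 px), bright inner band (2 px)
  paint_rect <- function(img, r0, r1, c0, c1, v) {
    r <- max(1L, r0):min(h, r1); cc <- max(1L, c0):min(w, c1)
    img[r, cc] <- v
    img
  }
  # top/bottom walls
  img <- paint_rect(img, y0 - 1L, y0, x0 - 1L, x1 + 2L, dark)
  img <- paint_rect(img, y0 + 1L, y0 + 2L, x0 + 1L, x1, bright)
  img <- paint_rect(img, y1 + 1L, y1 + 2L, x0 - 1L, x1 + 2L, dark)
  img <- paint_rect(img, y1 - 1L, y1, x0 + 1L, x1, bright)
  # left/right walls
  img <- paint_rect(img, y0 - 1L, y1 + 2L, x0 - 1L, x0, dark)
  img <- paint_rect(img, y0 + 1L, y1, x0 + 1L, x0 + 2L, bright)
  img <- paint_rect(img, y0 - 1L, y1 + 2L, x1 + 1L, x1 + 2L, dark)
  img <- paint_rect(img, y0 + 1L, y1, x1 - 1L, x1, bright)
  # outlet channels: gaps in the bottom wall with short flanking channel walls
  n_out <- layout$n_outlets
  gap_w <- max(6L, round((x1 - x0) * 0.08))
  centers <- x0 + (seq_len(n_out)) * (x1 - x0) / (n_out + 1L)
  for (cx in centers) {
    g0 <- round(cx - gap_w / 2); g1 <- round(cx + gap_w / 2)
    img <- paint_rect(img, y1 - 1L, y1 + 2L, g0 + 1L, g1, bg)   # open the gap
    img <- paint_rect(img, y1 + 1L, h, g0 - 1L, g0, dark)       # channel walls
    img <- paint_rect(img, y1 + 1L, h, g1 + 1L, g1 + 2L, dark)
  }
  list(img = img, interior = c(x0 + 2, y0 + 2, x1 - 2, y1 - 2))
}

# Render one textured cell disk: bright rim, darker annulus, mottled
# cytoplasm (the bright-field halo appearance at slight defocus). Returns the
# updated image and the tight box around the drawn pixels.
draw_cell <- function(img, cx, cy, r, rng_speckle) {
  h <- nrow(img); w <- ncol(img)
  j0 <- max(1L, floor(cx - r)); j1 <- min(w, ceiling(cx + r))
  i0 <- max(1L, floor(cy - r)); i1 <- min(h, ceiling(cy + r))
  jj <- j0:j1; ii <- i0:i1
  dx <- outer(rep(1, length(ii)), jj - 0.5 - cx)
  dy <- outer(ii - 0.5 - cy, rep(1, length(jj)))
  d <- sqrt(dx^2 + dy^2)
  inside <- d <= r
  patch <- img[ii, jj, drop = FALSE]
  rim <- inside & d > 0.78 * r
  ann <- d <= 0.78 * r & d > 0.45 * r
  core <- d <= 0.45 * r
  patch[rim] <- 0.88
  patch[ann] <- 0.30
  n_core <- sum(core)
  if (n_core > 0) patch[core] <- clamp01(0.52 + 0.07 * rng_speckle(n_core))
  img[ii, jj] <- patch
  # tight box in 0-based half-open coords from the drawn pixel extent
  cover <- which(inside, arr.ind = TRUE)
  box <- c(x_min = jj[min(cover[, 2])] - 1, y_min = ii[min(cover[, 1])] - 1,
           x_max = jj[max(cover[, 2])], y_max = ii[max(cover[, 1])])
  list(img = img, box = box)
}

# Rejection-sample n cell centers/radii inside the interior rectangle with
# minimum center distance 0.9 * (r_i + r_j) (touching clusters allowed).
place_cells <- function(interior, n, diam_mean, diam_sd, max_attempts = 400L) {
  cx <- numeric(0); cy <- numeric(0); r <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      ri <- max(2.5, stats::rnorm(1, diam_mean, diam_sd) / 2)
      lox <- interior[1] + ri; hix <- interior[3] - ri
      loy <- interior[2] + ri; hiy <- interior[4] - ri
      if (lox >= hix || loy >= hiy) next
      x <- stats::runif(1, lox, hix); y <- stats::runif(1, loy, hiy)
      if (length(cx) == 0L ||
          all(sqrt((cx - x)^2 + (cy - y)^2) >= 0.9 * (r + ri))) {
        cx <- c(cx, x); cy <- c(cy, y); r <- c(r, ri)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "could not place %d cells in the chamber after %d attempts each; chamber too small",
        n, max_attempts), call. = FALSE)
    }
  }
  data.frame(cx = cx, cy = cy, r = r)
}

# Scale contrast / add Gaussian noise so the image RSD (sd/mean over all
# pixels) matches `target`, then clip to [0, 1].
apply_target_rsd <- function(img, target) {
  m <- mean(img)
  base <- stats::sd(img) / m
  if (base > target) {
    img <- m + (img - m) * (0.97 * target / base)
    base <- stats::sd(img) / mean(img)
  }
  extra_var <- max(0, (target * m)^2 - stats::var(as.vector(img)))
  if (extra_var > 0) {
    img <- img + stats::rnorm(length(img), 0, sqrt(extra_var))
  }
  clamp01(img)
}

#' Generate one synthetic chamber scene with ground truth
#'
#' Renders a bright-field image of a microfluidic trap chamber: a visible
#' double-edge channel-wall contour, `n_cells` textured disks (bright rim,
#' darker annulus, mottled cytoplasm), Gaussian defocus blur, and noise
#' scaled so the per-image intensity RSD matches `spec$target_rsd`. Ground
#' truth is the tight axis-aligned box around each drawn disk.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `chip_scene`: a list with `pixels` (numeric
#'   matrix in `[0, 1]`), `boxes` (bounding-box data.frame), and `meta`
#'   (the spec plus `achieved_rsd` and per-cell centers/radii).
#' @examples
#' sc <- make_chamber_scene(scene_spec(n_cells = 3, seed = 42))
#' nrow(sc$boxes)
#' @export
make_chamber_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) spec <- do.call(scene_spec, spec)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(spec$seed, {
    img <- matrix(0.55, h, w)
    # gentle illumination gradient
    img <- img + outer(seq(-0.015, 0.015, length.out = h),
                       rep(1, w)) + outer(rep(1, h), seq(-0.01, 0.01, length.out = w))
    ch <- draw_chamber(img, chamber_layout(spec$chamber_type, h, w),
                       spec$wall_contrast)
    img <- ch$img
    cells <- place_cells(ch$interior, spec$n_cells,
                         spec$cell_diameter_px[1], spec$cell_diameter_px[2])
    boxes <- NULL
    for (i in seq_len(nrow(cells))) {
      dr <- draw_cell(img, cells$cx[i], cells$cy[i], cells$r[i], stats::rnorm)
      img <- dr$img
      boxes <- rbind(boxes, dr$box)
    }
    img <- gaussian_blur(img, spec$blur_sigma_px)
    img <- apply_target_rsd(img, spec$target_rsd)
    bx <- bounding_boxes(boxes[, "x_min"], boxes[, "y_min"],
                         boxes[, "x_max"], boxes[, "y_max"], label = "cell")
    structure(list(
      pixels = img,
      boxes = bx,
      meta = list(spec = spec, achieved_rsd = stats::sd(img) / mean(img),
                  cells = cells)
    ), class = "chip_scene")
  })
}

#' @export
print.chip_scene <- function(x, ...) {
  cat(sprintf("<chip_scene> %dx%d px, %d cells, achieved rsd %.3f\n",
              nrow(x$pixels), ncol(x$pixels), nrow(x$boxes),
              x$meta$achieved_rsd))
  invisible(x)
}

#' Generate a whole-array image of tiled chambers
#'
#' Tiles `grid_rows x grid_cols` chamber scenes (each drawn from `spec` with
#' a per-tile derived seed) on a common canvas, returning cell boxes in
#' global coordinates plus the chamber boxes themselves. Setting
#' `edge_shift_px > 0` shifts the top-left chamber partially off-canvas to
#' exercise downstream edge filtering; its chamber box is clipped to the
#' image bounds and flagged `edge = TRUE`.
#'
#' @param grid_rows,grid_cols Grid dimensions, `>= 1`.
#' @param spec A [scene_spec()] used for every tile (seeds vary per tile).
#' @param margin_px Background margin between and around chambers, `>= 0`.
#' @param edge_shift_px Shift of the first chamber up/left, in pixels.
#' @return A list with `scene` (a `chip_scene` whose `boxes` are all cell
#'   boxes in array coordinates) and `chamber_boxes` (data.frame with an
#'   `edge` logical column).
#' @export
make_array_image <- function(grid_rows, grid_cols, spec, margin_px = 8L,
                             edge_shift_px = 0L) {
  if (grid_rows < 1 || grid_cols < 1) stop("grid dimensions must be >= 1", call. = FALSE)
  if (margin_px < 0) stop("margin_px must be >= 0", call. = FALSE)
  ch_h <- spec$image_size[1]; ch_w <- spec$image_size[2]
  H <- grid_rows * ch_h + (grid_rows + 1L) * margin_px
  W <- grid_cols * ch_w + (grid_cols + 1L) * margin_px
  if (H < ch_h || W < ch_w) stop("canvas smaller than one chamber", call. = FALSE)
  canvas <- matrix(0.55, H, W)
  canvas <- with_seed((as.numeric(spec$seed) * 7919 + 13) %% 2147483647,
                      clamp01(canvas + stats::rnorm(length(canvas), 0, 0.02)))
  cell_boxes <- NULL
  chb <- NULL
  k <- 0L
  for (gr in seq_len(grid_rows)) {
    for (gc in seq_len(grid_cols)) {
      k <- k + 1L
      sub <- spec
      sub$seed <- as.integer((as.numeric(spec$seed) + 1000 * k) %% 2147483647)
      sc <- make_chamber_scene(sub)
      oy <- margin_px + (gr - 1L) * (ch_h + margin_px)
      ox <- margin_px + (gc - 1L) * (ch_w + margin_px)
      if (k == 1L && edge_shift_px > 0L) {
        oy <- oy - edge_shift_px; ox <- ox - edge_shift_px
      }
      # paste visible part
      src_r <- seq_len(ch_h); src_c <- seq_len(ch_w)
      dst_r <- oy + src_r; dst_c <- ox + src_c
      vis_r <- dst_r >= 1L & dst_r <= H; vis_c <- dst_c >= 1L & dst_c <= W
      canvas[dst_r[vis_r], dst_c[vis_c]] <- sc$pixels[src_r[vis_r], src_c[vis_c]]
      b <- sc$boxes
      if (nrow(b) > 0L) {
        b$x_min <- b$x_min + ox; b$x_max <- b$x_max + ox
        b$y_min <- b$y_min + oy; b$y_max <- b$y_max + oy
        b <- clip_boxes(b, W, H)
        cell_boxes <- rbind(cell_boxes, b)
      }
      cb <- data.frame(x_min = ox, y_min = oy, x_max = ox + ch_w,
                       y_max = oy + ch_h, label = "chamber",
                       confidence = NA_real_)
      clipped <- cb$x_min < 0 || cb$y_min < 0 || cb$x_max > W || cb$y_max > H
      cb <- clip_boxes(cb, W, H)
      cb$edge <- clipped
      chb <- rbind(chb, cb)
    }
  }
  rownames(chb) <- NULL
  scene <- structure(list(
    pixels = canvas,
    boxes = if (is.null(cell_boxes)) bounding_boxes() else cell_boxes,
    meta = list(spec = spec, grid = c(grid_rows, grid_cols),
                margin_px = margin_px, edge_shift_px = edge_shift_px,
                achieved_rsd = stats::sd(canvas) / mean(canvas))
  ), class = "chip_scene")
  list(scene = scene, chamber_boxes = chb)
}

#' Generate a synthetic time-lapse cell-killing assay
#'
#' Produces paired bright-field and fluorescence frames of one chamber over
#' time. Cells are trapped and immobile, so bright-field frames differ only
#' in their noise realization and share identical ground-truth boxes. Each
#' cell is live or dead per an absorbing-state schedule: the number dead at
#' frame `t` is `floor(kill_schedule[t] * n_cells)`, with dying cells chosen
#' at random among the still-live. Per-frame per-cell fluorescence is drawn
#' from `N(mu_live, sigma)` or `N(mu_dead, sigma)` (an apoptosis reporter:
#' dying cells brighten), giving a bimodal end-point histogram when
#' `mu_dead > mu_live + 4 * sigma` (the default).
#'
#' @param spec A [scene_spec()] for the chamber.
#' @param n_frames Number of timepoints.
#' @param kill_schedule Non-decreasing cumulative dead fractions in `[0,1]`,
#'   one per frame.
#' @param seed RNG seed (defaults to `spec$seed`).
#' @param mu_live,mu_dead,sigma Fluorescence intensity model (arbitrary
#'   units in `[0, 1]`).
#' @return An object of class `chip_assay`: `frames` (list of
#'   `list(brightfield, fluorescence)` matrices), `boxes` (ground truth,
#'   constant across frames), `states` (`n_cells x n_frames` character
#'   matrix, "live"/"dead"), `fluor_values` (true per-cell draw per frame),
#'   and `params`.
#' @export
make_timelapse_assay <- function(spec, n_frames, kill_schedule,
                                 seed = spec$seed,
                                 mu_live = 0.15, mu_dead = 0.85,
                                 sigma = 0.05) {
  if (length(kill_schedule) != n_frames) {
    stop("kill_schedule must have one entry per frame", call. = FALSE)
  }
  if (any(kill_schedule < 0 | kill_schedule > 1)) {
    stop("kill_schedule values must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(kill_schedule) < 0)) {
    stop("kill_schedule must be non-decreasing (dead is absorbing)", call. = FALSE)
  }
  if (mu_dead <= mu_live) stop("mu_dead must exceed mu_live", call. = FALSE)
  base <- make_chamber_scene(spec)
  n <- nrow(base$boxes)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(seed * 2654435761 %% 2147483647 + 1, {
    n_dead_t <- floor(kill_schedule * n)
    states <- matrix("live", n, n_frames)
    dead_set <- integer(0)
    for (t in seq_len(n_frames)) {
      need <- n_dead_t[t] - length(dead_set)
      if (need > 0) {
        alive <- setdiff(seq_len(n), dead_set)
        dead_set <- c(dead_set, sample(alive, need))
      }
      states[dead_set, t] <- "dead"
    }
    fluor_values <- matrix(NA_real_, n, n_frames)
    frames <- vector("list", n_frames)
    # structural bright-field image is regenerated identically, with a fresh
    # noise realization per frame
    for (t in seq_len(n_frames)) {
      bf <- base$pixels
      bf <- clamp01(bf + stats::rnorm(length(bf), 0, 0.01))
      fl <- matrix(0.02, h, w)
      for (i in seq_len(n)) {
        mu <- if (states[i, t] == "dead") mu_dead else mu_live
        v <- clamp01(stats::rnorm(1, mu, sigma))
        fluor_values[i, t] <- v
        b <- base$boxes[i, ]
        cc <- base$meta$cells[i, ]
        jj <- max(1L, floor(cc$cx - cc$r)):min(w, ceiling(cc$cx + cc$r))
        ii <- max(1L, floor(cc$cy - cc$r)):min(h, ceiling(cc$cy + cc$r))
        dxm <- outer(rep(1, length(ii)), jj - 0.5 - cc$cx)
        dym <- outer(ii - 0.5 - cc$cy, rep(1, length(jj)))
        inside <- sqrt(dxm^2 + dym^2) <= cc$r
        patch <- fl[ii, jj, drop = FALSE]
        patch[inside] <- v
        fl[ii, jj] <- patch
      }
      fl <- clamp01(fl + stats::rnorm(length(fl), 0, 0.008))
      frames[[t]] <- list(brightfield = bf, fluorescence = fl)
    }
    structure(list(
      frames = frames, boxes = base$boxes, states = states,
      fluor_values = fluor_values,
      params = list(spec = spec, n_frames = n_frames,
                    kill_schedule = kill_schedule,
                    mu_live = mu_live, mu_dead = mu_dead, sigma = sigma,
                    seed = seed)
    ), class = "chip_assay")
  })
}

#' @export
print.chip_assay <- function(x, ...) {
  cat(sprintf("<chip_assay> %d cells x %d frames, kill schedule [%s]\n",
              nrow(x$boxes), x$params$n_frames,
              paste(x$params$kill_schedule, collapse = ", ")))
  invisible(x)
}

#' Packing capacity of a chamber layout
#'
#' Largest cell count a layout can reliably hold by rejection sampling:
#' random sequential placement of disks jams near a packing fraction of
#' ~0.45, so the capacity is `0.45 * interior_area / disk_area` (at least 1).
#'
#' @param chamber_type Layout 1..4.
#' @param image_size `c(height, width)` in pixels.
#' @param cell_diameter_px Mean cell diameter in pixels.
#' @return Integer capacity.
#' @export
chamber_capacity <- function(chamber_type, image_size, cell_diameter_px) {
  h <- image_size[1]; w <- image_size[2]
  lay <- chamber_layout(chamber_type, h, w)
  iw <- w - 2 * (lay$inset_x + 2); ih <- h - 2 * (lay$inset_y + 2)
  r <- cell_diameter_px / 2
  max(1L, floor(0.45 * iw * ih / (pi * r^2)))
}

#' Sample a batch of random scene specifications
#'
#' Draws specs spanning the stated imaging conditions: all four chamber
#' layouts, 1-8 cells, target RSD uniform in `[0.15, 0.27]`, blur sigma in
#' `[0.5, 1.6]`, and lymphoblast-scale diameters.
#'
#' @param n Number of specs.
#' @param seed RNG seed.
#' @param n_cells_range Integer range to sample cell counts from.
#' @param image_size Passed to every spec.
#' @return A list of [scene_spec()] objects with distinct seeds.
#' @export
random_scene_specs <- function(n, seed = 1L, n_cells_range = c(1L, 8L),
                               image_size = c(100L, 200L)) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ct <- sample(1:4, 1)
      diam <- stats::runif(1, 18, 26)
      cap <- chamber_capacity(ct, image_size, diam)
      hi <- max(n_cells_range[1], min(n_cells_range[2], cap))
      scene_spec(
        image_size = image_size,
        chamber_type = ct,
        n_cells = sample(seq(n_cells_range[1], hi), 1),
        cell_diameter_px = c(diam, 2),
        wall_contrast = stats::runif(1, 0.25, 0.4),
        blur_sigma_px = stats::runif(1, 0.5, 1.6),
        target_rsd = stats::runif(1, 0.15, 0.27),
        seed = as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
      )
    })
  })
}

#' Generate a list of annotated scenes
#'
#' Convenience wrapper: [random_scene_specs()] piped through
#' [make_chamber_scene()].
#'
#' @inheritParams random_scene_specs
#' @return A list of `chip_scene` objects.
#' @export
synth_dataset <- function(n, seed = 1L, n_cells_range = c(1L, 8L),
                          image_size = c(100L, 200L)) {
  lapply(random_scene_specs(n, seed, n_cells_range, image_size),
         make_chamber_scene)
}
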