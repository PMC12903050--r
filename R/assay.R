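#' Total cell count at the first timepoint
#'
#' Cells are trapped in chambers and cannot escape, so the total cell count
#' in the array is constant over the assay. `N_total` is fixed at t0 as the
#' number of detections at or above the confidence cutoff (default 0.9).
#'
#' @param dets_t0 Detections at t0 (with confidences).
#' @param conf Confidence cutoff, default 0.9.
#' @return Integer count.
#' @export
count_t0 <- function(dets_t0, conf = 0.9) {
  nrow(filter_by_confidence(dets_t0, conf))
}

#' Constant-count detection at later timepoints
#'
#' At timepoints after t0 the confidence cutoff is lowered so that the
#' number of detections matches `N_total` — implemented as exact top-N
#' selection by confidence (ties broken by `x_min`, then `y_min`). The
#' confidence of the last kept box is reported as the effective threshold.
#' If fewer than `n_total` raw detections exist, all are returned and the
#' shortfall is flagged.
#'
#' @param dets_t Detections at one timepoint.
#' @param n_total Target count from [count_t0()].
#' @return List with `detections`, `effective_threshold`, and `shortfall`
#'   (number of missing detections, 0 when none).
#' @export
select_constant_count <- function(dets_t, n_total) {
  if (n_total < 0) stop("n_total must be >= 0", call. = FALSE)
  o <- order(-dets_t$confidence, dets_t$x_min, dets_t$y_min)
  k <- min(n_total, nrow(dets_t))
  sel <- dets_t[o[seq_len(k)], , drop = FALSE]
  rownames(sel) <- NULL
  shortfall <- n_total - k
  if (shortfall > 0) {
    warning(sprintf("only %d of the requested %d detections available",
                    k, n_total))
  }
  eff <- if (k > 0L) sel$confidence[k] else NA_real_
  attr(sel, "image_id") <- attr(dets_t, "image_id")
  attr(sel, "model") <- attr(dets_t, "model")
  attr(sel, "threshold") <- eff
  class(sel) <- class(dets_t)
  list(detections = sel, effective_threshold = eff, shortfall = shortfall)
}

#' Mean fluorescence inside a detection box
#'
#' Arithmetic mean of the fluorescence pixels inside the half-open box
#' (pixel column `j` is inside iff `x_min <= j - 1 < x_max`).
#'
#' @param box Single-row bounding-box data.frame or `c(x_min, y_min, x_max,
#'   y_max)`.
#' @param fluor_image Numeric matrix.
#' @return Mean intensity (arbitrary units).
#' @export
roi_mean_fluorescence <- function(box, fluor_image) {
  b <- as_box_vec(box)
  h <- nrow(fluor_image); w <- ncol(fluor_image)
  if (b[1] < 0 || b[2] < 0 || b[3] > w || b[4] > h) {
    stop("box extends outside the fluorescence image", call. = FALSE)
  }
  jj <- (floor(b[1]) + 1L):ceiling(b[3])
  ii <- (floor(b[2]) + 1L):ceiling(b[4])
  mean(fluor_image[ii, jj])
}

#' Live/dead threshold from a bimodal fluorescence histogram
#'
#' At the assay end point the per-cell fluorescence histogram is bimodal
#' (live mode low, dying mode high); the local minimum between the two
#' peaks is the live/dead threshold. The histogram has `n_bins` bins over
#' `[min, max]`, is smoothed with a 3-bin moving average, the two highest
#' local maxima are located, and the center of the lowest bin strictly
#' between them is returned.
#'
#' @param values Numeric vector of per-cell mean fluorescences (>= 10).
#' @param n_bins Number of histogram bins (default 50).
#' @return The threshold (bin center).
#' @export
bimodal_threshold <- function(values, n_bins = 50L) {
  if (length(values) < 10L) stop("need at least 10 values", call. = FALSE)
  r <- range(values)
  if (diff(r) == 0) {
    stop("histogram is unimodal (all values identical); choose a manual threshold",
         call. = FALSE)
  }
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  hh <- graphics::hist(values, breaks = br, plot = FALSE)
  counts <- as.numeric(hh$counts)
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm[1] <- mean(counts[1:2]); sm[n_bins] <- mean(counts[(n_bins - 1):n_bins])
  sm <- as.numeric(sm)
  # interior local maxima (plateau-tolerant on the left side)
  is_peak <- vapply(seq_len(n_bins), function(i) {
    left <- if (i == 1L) -Inf else sm[i - 1L]
    right <- if (i == n_bins) -Inf else sm[i + 1L]
    sm[i] > left && sm[i] >= right
  }, TRUE)
  peaks <- which(is_peak)
  if (length(peaks) < 2L) {
    stop("histogram is unimodal: no local minimum between two peaks; choose a manual threshold",
         call. = FALSE)
  }
  # the primary peak is the global maximum; the partner peak is the local
  # maximum with the deepest valley between it and the primary (a bumpy
  # single mode yields shallow valleys, two real modes a deep one)
  p1 <- peaks[which.max(sm[peaks])]
  depth <- vapply(peaks, function(j) {
    if (abs(j - p1) < 2L) return(-Inf)
    seg <- (min(p1, j) + 1L):(max(p1, j) - 1L)
    min(sm[p1], sm[j]) - min(sm[seg])
  }, numeric(1))
  rel_depth <- depth / pmin(sm[p1], sm[peaks])
  # a genuine second mode must carry weight (>= 10% of the primary peak)
  # and be separated by a pronounced valley; tail wiggles satisfy neither
  admissible <- is.finite(depth) & rel_depth > 0.5 & sm[peaks] >= 0.1 * sm[p1]
  if (!any(admissible)) {
    stop("histogram is unimodal: no local minimum between two peaks; choose a manual threshold",
         call. = FALSE)
  }
  p2 <- peaks[which.max(ifelse(admissible, depth, -Inf))]
  lo <- min(p1, p2); hi <- max(p1, p2)
  between <- (lo + 1L):(hi - 1L)
  ties <- between[sm[between] == min(sm[between])]
  # well-separated modes leave a flat minimal plateau; among tied minimal
  # bins take the one nearest the midpoint of the two peaks, the stable
  # estimate of the density crossing
  mid <- (p1 + p2) / 2
  vmin <- ties[which.min(abs(ties - mid))]
  hh$mids[vmin]
}

#' Link per-timepoint detections into cell trajectories
#'
#' Cells are trapped and near-stationary, so trajectories are built by
#' greedy nearest-center matching between consecutive timepoints, accepting
#' a link only when the center displacement is at most `max_disp_px`.
#' Unmatched boxes start new trajectories; trajectories that find no match
#' terminate and are flagged incomplete.
#'
#' @param per_timepoint_boxes Time-ordered list of detection sets (or box
#'   data.frames).
#' @param max_disp_px Maximum allowed center displacement per step.
#' @return List of `cell_trajectory` objects: `id`, `t` (timepoint
#'   indices), `boxes` (one row per timepoint present), `complete` (spans
#'   every timepoint).
#' @export
build_trajectories <- function(per_timepoint_boxes, max_disp_px = 5) {
  nt <- length(per_timepoint_boxes)
  if (nt == 0L) return(list())
  centers <- function(b) cbind((b$x_min + b$x_max) / 2, (b$y_min + b$y_max) / 2)
  trajs <- list()
  b1 <- as.data.frame(per_timepoint_boxes[[1]])
  open <- seq_len(nrow(b1))   # trajectory index open at current timepoint
  for (i in seq_len(nrow(b1))) {
    trajs[[i]] <- list(id = i, t = 1L, boxes = b1[i, , drop = FALSE])
  }
  for (t in seq_len(nt - 1L)) {
    cur <- as.data.frame(per_timepoint_boxes[[t]])
    nxt <- as.data.frame(per_timepoint_boxes[[t + 1L]])
    # current boxes of open trajectories
    open_idx <- which(vapply(trajs, function(tr) utils::tail(tr$t, 1) == t, TRUE))
    if (length(open_idx) > 0L && nrow(nxt) > 0L) {
      cc <- do.call(rbind, lapply(trajs[open_idx], function(tr)
        centers(utils::tail(tr$boxes, 1))))
      cn <- centers(nxt)
      D <- sqrt(outer(cc[, 1], cn[, 1], `-`)^2 + outer(cc[, 2], cn[, 2], `-`)^2)
      used_next <- logical(nrow(nxt))
      # greedy: smallest displacement first
      repeat {
        D_ok <- D
        D_ok[, used_next] <- Inf
        m <- which(D_ok == min(D_ok), arr.ind = TRUE)
        if (!is.finite(min(D_ok)) || min(D_ok) > max_disp_px) break
        i <- m[1, 1]; j <- m[1, 2]
        k <- open_idx[i]
        trajs[[k]]$t <- c(trajs[[k]]$t, t + 1L)
        trajs[[k]]$boxes <- rbind(trajs[[k]]$boxes, nxt[j, , drop = FALSE])
        used_next[j] <- TRUE
        D[i, ] <- Inf
      }
      for (j in which(!used_next)) {
        trajs[[length(trajs) + 1L]] <- list(id = length(trajs) + 1L,
                                            t = t + 1L,
                                            boxes = nxt[j, , drop = FALSE])
      }
    } else if (nrow(nxt) > 0L) {
      for (j in seq_len(nrow(nxt))) {
        trajs[[length(trajs) + 1L]] <- list(id = length(trajs) + 1L,
                                            t = t + 1L,
                                            boxes = nxt[j, , drop = FALSE])
      }
    }
  }
  lapply(trajs, function(tr) {
    rownames(tr$boxes) <- NULL
    tr$complete <- length(tr$t) == nt
    class(tr) <- "cell_trajectory"
    tr
  })
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat(sprintf("<cell_trajectory> id=%d, %d timepoints%s\n", x$id,
              length(x$t), if (x$complete) "" else " (incomplete)"))
  invisible(x)
}

#' Attach per-timepoint fluorescence to trajectories
#'
#' @param trajectories Output of [build_trajectories()].
#' @param fluor_frames Time-ordered list of fluorescence matrices.
#' @return The trajectories, each with a `fluor` vector added.
#' @export
measure_trajectories <- function(trajectories, fluor_frames) {
  lapply(trajectories, function(tr) {
    tr$fluor <- vapply(seq_along(tr$t), function(k) {
      roi_mean_fluorescence(tr$boxes[k, ], fluor_frames[[tr$t[k]]])
    }, numeric(1))
    tr
  })
}

#' Survival curve from fluorescence trajectories
#'
#' A cell is called dead at timepoint `t` iff its mean fluorescence is at or
#' above `threshold` (the apoptosis reporter brightens in dying cells). The
#' live fraction at `t` is `live(t) / N_total`. With
#' `absorbing = TRUE` (default, matching the constant-trap assumption) a
#' cell stays dead once called dead.
#'
#' @param trajectories Trajectories with `fluor` (see
#'   [measure_trajectories()]).
#' @param threshold Live/dead fluorescence threshold (see
#'   [bimodal_threshold()]).
#' @param n_total `N_total`; defaults to the number of trajectories.
#' @param absorbing Enforce the absorbing dead state.
#' @return An object of class `assay_result`: data.frame `curve`
#'   (`t, n_live, live_fraction`), plus `threshold`, `n_total`, and the
#'   per-cell state matrix.
#' @export
survival_curve <- function(trajectories, threshold,
                           n_total = length(trajectories),
                           absorbing = TRUE) {
  if (length(trajectories) == 0L) stop("no trajectories", call. = FALSE)
  nt <- max(unlist(lapply(trajectories, function(tr) max(tr$t))))
  states <- matrix(NA_character_, length(trajectories), nt)
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    if (is.null(tr$fluor)) stop("trajectories carry no fluorescence; run measure_trajectories()", call. = FALSE)
    dead <- FALSE
    for (k in seq_along(tr$t)) {
      d_now <- tr$fluor[k] >= threshold
      dead <- if (absorbing) dead || d_now else d_now
      states[i, tr$t[k]] <- if (dead) "dead" else "live"
    }
  }
  n_live <- vapply(seq_len(nt), function(t) sum(states[, t] == "live", na.rm = TRUE), 1L)
  curve <- data.frame(t = seq_len(nt), n_live = n_live,
                      live_fraction = n_live / n_total)
  structure(list(curve = curve, threshold = threshold, n_total = n_total,
                 states = states, absorbing = absorbing),
            class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf("<assay_result> N_total=%d, threshold=%.3f\n", x$n_total,
              x$threshold))
  print(x$curve)
  invisible(x)
}

#' Quantify a cell-killing assay end to end
#'
#' The full analysis chain on per-timepoint bright-field detections and
#' fluorescence frames: `N_total` at t0 (confidence cutoff `conf`),
#' constant-count selection at later timepoints, trajectory building,
#' per-cell ROI fluorescence, live/dead threshold from the bimodal
#' end-point histogram (unless supplied), and the survival curve.
#'
#' @param dets_per_t Time-ordered list of detection sets on the bright-field
#'   frames.
#' @param fluor_frames Time-ordered list of fluorescence matrices.
#' @param conf Confidence cutoff at t0 (default 0.9).
#' @param max_disp_px Trajectory linking limit.
#' @param threshold Optional manual live/dead threshold.
#' @param n_bins Histogram bins for [bimodal_threshold()].
#' @return An `assay_result`, with the effective per-timepoint thresholds in
#'   `$effective_thresholds` and the trajectories in `$trajectories`.
#' @export
run_assay <- function(dets_per_t, fluor_frames, conf = 0.9, max_disp_px = 5,
                      threshold = NULL, n_bins = 50L) {
  nt <- length(dets_per_t)
  if (nt != length(fluor_frames)) {
    stop("detections and fluorescence frames must align", call. = FALSE)
  }
  n_total <- count_t0(dets_per_t[[1]], conf)
  sel <- vector("list", nt)
  eff <- numeric(nt)
  sel[[1]] <- filter_by_confidence(dets_per_t[[1]], conf)
  eff[1] <- conf
  if (nt > 1L) {
    for (t in 2:nt) {
      s <- select_constant_count(dets_per_t[[t]], n_total)
      sel[[t]] <- s$detections
      eff[t] <- s$effective_threshold
    }
  }
  trajs <- build_trajectories(sel, max_disp_px)
  trajs <- measure_trajectories(trajs, fluor_frames)
  if (is.null(threshold)) {
    endpoint <- unlist(lapply(trajs, function(tr) {
      k <- which(tr$t == nt)
      if (length(k)) tr$fluor[k] else NULL
    }))
    threshold <- bimodal_threshold(endpoint, n_bins)
  }
  res <- survival_curve(trajs, threshold, n_total = n_total)
  res$effective_thresholds <- eff
  res$trajectories <- trajs
  res
}
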