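#' Training configuration for the cell detector
#'
#' The detector is a two-stage region-proposal model: a multi-scale
#' circular-gradient proposal stage generates candidate boxes, and a
#' trainable head scores each candidate (logistic classification) and
#' refines its box (linear regression). Training runs full-batch gradient
#' descent with momentum and terminates once the epoch budget has been run
#' *and* the trailing `window`-epoch mean of the total loss has fallen
#' below `stop_loss` — training is considered converged when the total loss
#' plateaus at ~0.15 after the budgeted epochs (hard cap at twice the
#' budget if the plateau never reaches `stop_loss`).
#'
#' @param epochs Epoch budget (default 200): the minimum number of epochs
#'   run before the plateau criterion is consulted.
#' @param stop_loss Plateau level of the total loss at which training stops
#'   (default 0.15).
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param l2 L2 weight penalty.
#' @param window Trailing-window length for the stopping rule.
#' @param augment_flip Horizontal-flip augmentation of training patches.
#' @param patch_size Side of the square feature patch each candidate box is
#'   resampled to.
#' @param seed RNG seed for proposal sampling / augmentation order.
#' @param classes Class list (single "cell" class by default).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, stop_loss = 0.15, lr = 0.2,
                         momentum = 0.9, l2 = 1e-3, window = 10L,
                         augment_flip = TRUE, patch_size = 12L,
                         seed = 1L, classes = "cell") {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (stop_loss <= 0) stop("stop_loss must be > 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs), stop_loss = stop_loss,
                 lr = lr, momentum = momentum, l2 = l2,
                 window = as.integer(window), augment_flip = augment_flip,
                 patch_size = as.integer(patch_size), seed = as.integer(seed),
                 classes = classes),
            class = "train_config")
}

# min-max normalize an image to [0, 1] (flat images map to 0).
norm_image <- function(img) {
  r <- range(img)
  if (diff(r) == 0) return(img * 0)
  (img - r[1]) / diff(r)
}

# Stage 1: multi-scale region proposals. For each candidate radius, the
# Sobel gradient magnitude is correlated with a one-pixel-wide ring kernel
# (normalized by ring length); cells present a closed gradient rim at their
# radius, so the response peaks at cell centers at the matching scale.
# Returns data.frame(cx, cy, r, score) of local maxima of the per-pixel
# best-scale response.
propose_regions <- function(img, radii, max_proposals = 150L,
                            min_rel_score = 0.15) {
  img <- norm_image(img)
  h <- nrow(img); w <- ncol(img)
  g <- sobel_magnitude(img)
  stack <- lapply(radii, function(r) {
    xcorr_fft(g, embed_kernel(ring_kernel(r), h, w))
  })
  best <- Reduce(pmax, stack)
  thr <- max(best) * min_rel_score
  pk <- local_maxima(best, k = 2L, thr = max(thr, 1e-9))
  if (nrow(pk) > max_proposals) pk <- pk[seq_len(max_proposals), , drop = FALSE]
  if (nrow(pk) == 0L) {
    return(data.frame(cx = numeric(), cy = numeric(), r = numeric(),
                      score = numeric()))
  }
  # a textured cell excites ring responses at its internal edges too
  # (annulus/core boundaries); the outer contour is the largest radius with
  # near-maximal response at the peak location
  r_hat <- vapply(seq_len(nrow(pk)), function(i) {
    resp_r <- vapply(stack, function(m) m[pk$row[i], pk$col[i]], numeric(1))
    radii[max(which(resp_r >= 0.8 * max(resp_r)))]
  }, numeric(1))
  data.frame(cx = pk$col - 0.5, cy = pk$row - 0.5, r = r_hat,
             score = pk$value)
}

# One-pixel ring kernel of radius r, values normalized to sum 1.
ring_kernel <- function(r) {
  half <- ceiling(r) + 1L
  x <- (-half):half
  d <- sqrt(outer(x^2, x^2, `+`))
  k <- as.numeric(abs(d - r) <= 0.6)
  m <- matrix(k, length(x), length(x))
  m / sum(m)
}

# Precomputed polar-coordinate index masks for an S x S patch: 4 concentric
# rings and 8 angular sectors of the outer half. Cached per S.
polar_masks <- local({
  cache <- list()
  function(S) {
    key <- as.character(S)
    if (!is.null(cache[[key]])) return(cache[[key]])
    c0 <- (S + 1) / 2
    xs <- outer(rep(1, S), seq_len(S)) - c0
    ys <- outer(seq_len(S), rep(1, S)) - c0
    d <- sqrt(xs^2 + ys^2) / (S / 2)
    ang <- atan2(ys, xs)
    rings <- lapply(1:4, function(k) d > (k - 1) / 4 & d <= k / 4)
    sectors <- lapply(1:8, function(k) {
      lo <- -pi + (k - 1) * pi / 4; hi <- -pi + k * pi / 4
      ang > lo & ang <= hi & d > 0.5 & d <= 1
    })
    out <- list(rings = rings, sectors = sectors)
    cache[[key]] <<- out
    out
  }
})

# Resample the (context-expanded) box region of `img` to an S x S patch by
# nearest-neighbor lookup. Features: the standardized patch pixels, log box
# area, patch contrast relative to the image, 4 concentric ring means
# (radial profile), and the angular variance of the outer-ring sector means
# (low for radially symmetric cells, high for wall corners and line
# segments).
patch_features <- function(img, box, S, expand = 1.25) {
  h <- nrow(img); w <- ncol(img)
  cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
  bw <- (box[3] - box[1]) * expand; bh <- (box[4] - box[2]) * expand
  xs <- cx + (seq_len(S) - (S + 1) / 2) / S * bw
  ys <- cy + (seq_len(S) - (S + 1) / 2) / S * bh
  jj <- pmin(w, pmax(1L, ceiling(xs)))
  ii <- pmin(h, pmax(1L, ceiling(ys)))
  patch <- img[ii, jj, drop = FALSE]
  s <- stats::sd(patch)
  img_s <- stats::sd(img)
  z <- if (s > 0) (patch - mean(patch)) / s else patch * 0
  pm <- polar_masks(S)
  ring_means <- vapply(pm$rings, function(m) mean(z[m]), numeric(1))
  sector_means <- vapply(pm$sectors, function(m) mean(z[m]), numeric(1))
  c(as.numeric(z),
    log((box[3] - box[1]) * (box[4] - box[2])) / 10,
    if (img_s > 0) min(s / img_s, 4) else 0,
    ring_means,
    stats::var(sector_means))
}

feature_dim <- function(S) S * S + 7L

# Assemble the training design matrix from proposals + ground truth.
# Positives: candidates with IoU >= 0.5 against some GT (the GT boxes
# themselves and small jitters of them are always included so sparse
# annotations still yield positives). Negatives: candidates with max
# IoU < 0.3. Mid-range candidates are discarded, as is standard for
# region-proposal head training. Regression targets are offsets from the
# candidate to its matched GT.
build_training_set <- function(dataset, radii, cfg) {
  S <- cfg$patch_size
  X <- NULL; y <- integer(0); Treg <- NULL; reg_mask <- logical(0)
  for (sc in dataset) {
    img <- norm_image(sc$pixels)
    gt <- sc$boxes
    props <- propose_regions(sc$pixels, radii)
    cand <- NULL
    if (nrow(props) > 0L) {
      cand <- data.frame(
        x_min = props$cx - props$r, y_min = props$cy - props$r,
        x_max = props$cx + props$r, y_max = props$cy + props$r)
    }
    # GT boxes + jittered copies as guaranteed positives
    for (i in seq_len(nrow(gt))) {
      b <- as.numeric(gt[i, c("x_min", "y_min", "x_max", "y_max")])
      wdt <- b[3] - b[1]; hgt <- b[4] - b[2]
      for (rep in 1:3) {
        jit <- b + stats::runif(4, -0.08, 0.08) * c(wdt, hgt, wdt, hgt)
        cand <- rbind(cand, data.frame(x_min = jit[1], y_min = jit[2],
                                       x_max = jit[3], y_max = jit[4]))
      }
    }
    # random background boxes so walls, outlets and corners enter the
    # negative pool even where the proposer is quiet
    hh <- nrow(img); ww <- ncol(img)
    for (rep in seq_len(40L)) {
      r <- radii[sample.int(length(radii), 1)]
      rcx <- stats::runif(1, r, ww - r); rcy <- stats::runif(1, r, hh - r)
      cand <- rbind(cand, data.frame(x_min = rcx - r, y_min = rcy - r,
                                     x_max = rcx + r, y_max = rcy + r))
    }
    if (is.null(cand) || nrow(cand) == 0L) next
    cand <- clip_boxes(cand, ncol(img), nrow(img))
    M <- iou_matrix(cand, gt)
    best_iou <- if (ncol(M) > 0L) apply(M, 1, max) else rep(0, nrow(cand))
    best_gt <- if (ncol(M) > 0L) apply(M, 1, which.max) else rep(NA_integer_, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      lab <- if (best_iou[i] >= 0.5) 1L else if (best_iou[i] < 0.3) 0L else NA_integer_
      if (is.na(lab)) next
      b <- as.numeric(cand[i, 1:4])
      f <- patch_features(img, b, S)
      X <- rbind(X, f); y <- c(y, lab)
      if (lab == 1L) {
        g <- as.numeric(gt[best_gt[i], c("x_min", "y_min", "x_max", "y_max")])
        bw <- b[3] - b[1]; bh <- b[4] - b[2]
        Treg <- rbind(Treg, c(((g[1] + g[3]) - (b[1] + b[3])) / 2 / bw,
                              ((g[2] + g[4]) - (b[2] + b[4])) / 2 / bh,
                              log((g[3] - g[1]) / bw),
                              log((g[4] - g[2]) / bh)))
        reg_mask <- c(reg_mask, TRUE)
      } else {
        Treg <- rbind(Treg, c(0, 0, 0, 0))
        reg_mask <- c(reg_mask, FALSE)
      }
    }
  }
  if (is.null(X) || sum(y) == 0L) {
    stop("training set yielded no positive candidates", call. = FALSE)
  }
  if (cfg$augment_flip) {
    S2 <- S * S
    flip_rows <- function(X0, T0, fx, fy) {
      Xf <- X0
      for (i in seq_len(nrow(X0))) {
        pm <- matrix(X0[i, seq_len(S2)], S, S)
        if (fx) pm <- pm[, S:1]
        if (fy) pm <- pm[S:1, ]
        Xf[i, seq_len(S2)] <- as.numeric(pm)
      }
      Tf <- T0
      if (fx) Tf[, 1] <- -Tf[, 1]
      if (fy) Tf[, 2] <- -Tf[, 2]
      list(X = Xf, T = Tf)
    }
    aug <- list(flip_rows(X, Treg, TRUE, FALSE),
                flip_rows(X, Treg, FALSE, TRUE),
                flip_rows(X, Treg, TRUE, TRUE))
    for (a in aug) {
      X <- rbind(X, a$X); Treg <- rbind(Treg, a$T)
    }
    y <- rep(y, 4L); reg_mask <- rep(reg_mask, 4L)
  }
  list(X = X, y = y, Treg = Treg, reg_mask = reg_mask)
}

#' Train the cell detector
#'
#' Fits the classification/refinement head on region proposals harvested
#' from the training images (stage-1 scale anchors are derived from the
#' ground-truth box sizes). The head starts from a fixed generic
#' initialization (zeros) and is optimized by seeded full-batch gradient
#' descent with momentum; the per-epoch total loss (classification
#' cross-entropy) is recorded, and training stops at `min(epochs, first
#' epoch whose trailing-window mean loss < stop_loss)`. The box-refinement
#' regressors are then fit in closed form (ridge) on the positive
#' candidates.
#'
#' @param dataset Non-empty list of `chip_scene` objects (or lists with
#'   `pixels` and `boxes`); every image must have at least one box.
#' @param config A [train_config()].
#' @return A list with `model` (class `chip_detector`) and `loss_history`
#'   (numeric vector, one total loss per epoch run).
#' @export
train_detector <- function(dataset, config = train_config()) {
  if (length(dataset) == 0L) stop("training dataset is empty", call. = FALSE)
  for (sc in dataset) {
    if (is.null(sc$boxes) || nrow(sc$boxes) == 0L) {
      stop("every training image must have at least one annotation", call. = FALSE)
    }
  }
  # scale anchors from annotated box sizes
  sizes <- unlist(lapply(dataset, function(sc)
    (sc$boxes$x_max - sc$boxes$x_min + sc$boxes$y_max - sc$boxes$y_min) / 4))
  lo <- 0.75 * min(sizes); hi <- 1.35 * max(sizes)
  radii <- unique(round(seq(lo, hi, by = max(1, (hi - lo) / 13)), 1))
  with_seed(config$seed, {
    ts <- build_training_set(dataset, radii, config)
    X <- ts$X; y <- ts$y
    n <- nrow(X); p <- ncol(X)
    mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    w <- rep(0, p); b <- 0
    vw <- rep(0, p); vb <- 0
    pos <- ts$reg_mask
    loss_history <- numeric(0)
    # terminate once the epoch budget has been run AND the trailing-window
    # mean loss has plateaued below stop_loss (hard cap at 2x the budget)
    for (ep in seq_len(2L * config$epochs)) {
      z <- as.numeric(Xs %*% w) + b
      pr <- 1 / (1 + exp(-z))
      eps <- 1e-12
      ce <- -mean(y * log(pr + eps) + (1 - y) * log(1 - pr + eps))
      grad_z <- (pr - y) / n
      gw <- as.numeric(crossprod(Xs, grad_z)) + config$l2 * w
      gb <- sum(grad_z)
      vw <- config$momentum * vw - config$lr * gw
      vb <- config$momentum * vb - config$lr * gb
      w <- w + vw; b <- b + vb
      loss_history <- c(loss_history, ce)
      if (ep >= config$epochs &&
          mean(utils::tail(loss_history, config$window)) < config$stop_loss) break
    }
    # refinement head: ridge regression on positive candidates
    W_reg <- matrix(0, p + 1L, 4L)
    if (sum(pos) >= 4L) {
      Xp <- cbind(1, Xs[pos, , drop = FALSE])
      Tp <- ts$Treg[pos, , drop = FALSE]
      A <- crossprod(Xp) + diag(1e-2, ncol(Xp))
      W_reg <- solve(A, crossprod(Xp, Tp))
    }
    model <- structure(list(
      w = w, b = b, W_reg = W_reg, feat_mean = mu, feat_sd = sdv,
      radii = radii, classes = config$classes, patch_size = config$patch_size,
      provenance = list(
        config = unclass(config),
        n_train_images = length(dataset),
        n_annotations = sum(vapply(dataset, function(s) nrow(s$boxes), 1L)),
        dataset_hash = dataset_hash(dataset),
        final_loss = utils::tail(loss_history, 1))
    ), class = "chip_detector")
    list(model = model, loss_history = loss_history)
  })
}

dataset_hash <- function(dataset) {
  v <- unlist(lapply(dataset, function(s) c(dim(s$pixels), nrow(s$boxes),
                                            sum(s$pixels))))
  sprintf("%08x", sum(round(v * 1e3)) %% 4294967291)
}

#' @export
print.chip_detector <- function(x, ...) {
  cat(sprintf(
    "<chip_detector> classes=[%s], %d features, scale anchors [%s] px, trained on %d images / %d annotations (final loss %.4f)\n",
    paste(x$classes, collapse = ","), length(x$w),
    paste(x$radii, collapse = ", "), x$provenance$n_train_images,
    x$provenance$n_annotations, x$provenance$final_loss))
  invisible(x)
}

#' Run detector inference on one image
#'
#' Deterministic (no RNG): proposals are generated at the model's scale
#' anchors, scored by the classification head, refined by the regression
#' head, and deduplicated by non-maximum suppression. Returns *all* raw
#' detections (no confidence cutoff); apply [filter_by_confidence()] (the
#' pipeline default cutoff is 0.9) separately.
#'
#' @param model A `chip_detector`.
#' @param image Numeric matrix (single channel; a `h x w x 3` array is
#'   averaged to one channel).
#' @param image_id Identifier recorded on the output.
#' @param nms_iou IoU above which overlapping detections are suppressed.
#' @return A `chip_detections` object.
#' @export
infer <- function(model, image, image_id = "image", nms_iou = 0.45) {
  if (!inherits(model, "chip_detector")) stop("not a chip_detector", call. = FALSE)
  if (is.array(image) && length(dim(image)) == 3L) {
    image <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  }
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix (or h x w x 3 array)", call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  img <- norm_image(image)
  props <- propose_regions(image, model$radii)
  if (nrow(props) == 0L) {
    return(detection_set(bounding_boxes(), image_id = image_id,
                         model = "chip_detector"))
  }
  S <- model$patch_size
  boxes <- NULL
  for (i in seq_len(nrow(props))) {
    b <- c(props$cx[i] - props$r[i], props$cy[i] - props$r[i],
           props$cx[i] + props$r[i], props$cy[i] + props$r[i])
    b <- c(max(b[1], 0), max(b[2], 0), min(b[3], w), min(b[4], h))
    if (b[3] <= b[1] || b[4] <= b[2]) next
    f <- (patch_features(img, b, S) - model$feat_mean) / model$feat_sd
    conf <- 1 / (1 + exp(-(sum(f * model$w) + model$b)))
    d <- as.numeric(c(1, f) %*% model$W_reg)
    bw <- b[3] - b[1]; bh <- b[4] - b[2]
    cx <- (b[1] + b[3]) / 2 + d[1] * bw
    cy <- (b[2] + b[4]) / 2 + d[2] * bh
    nw <- bw * exp(max(min(d[3], 0.5), -0.5))
    nh <- bh * exp(max(min(d[4], 0.5), -0.5))
    nb <- c(cx - nw / 2, cy - nh / 2, cx + nw / 2, cy + nh / 2)
    nb <- c(max(nb[1], 0), max(nb[2], 0), min(nb[3], w), min(nb[4], h))
    if (nb[3] <= nb[1] || nb[4] <= nb[2]) next
    boxes <- rbind(boxes, data.frame(
      x_min = nb[1], y_min = nb[2], x_max = nb[3], y_max = nb[4],
      label = model$classes[1], confidence = conf))
  }
  if (is.null(boxes)) {
    return(detection_set(bounding_boxes(), image_id = image_id,
                         model = "chip_detector"))
  }
  boxes <- nms_boxes(boxes, nms_iou)
  detection_set(boxes, image_id = image_id, model = "chip_detector")
}

# Greedy non-maximum suppression by descending confidence.
nms_boxes <- function(boxes, iou_cut) {
  o <- order(-boxes$confidence, boxes$x_min, boxes$y_min)
  boxes <- boxes[o, , drop = FALSE]
  keep <- logical(nrow(boxes))
  M <- iou_matrix(boxes, boxes)
  for (i in seq_len(nrow(boxes))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    keep[i] <- all(M[i, which(keep)] <= iou_cut)
  }
  out <- boxes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Save / load a detector checkpoint
#'
#' The checkpoint is a single JSON archive embedding the weights, scale
#' anchors, class list, and training provenance (config, dataset manifest
#' hash), so a run is fully reproducible from its artifact.
#'
#' @param model A `chip_detector`.
#' @param path Checkpoint path (JSON).
#' @return `path` / the restored `chip_detector`.
#' @export
save_detector <- function(model, path) {
  payload <- list(
    format = "chipcell-detector-v1",
    w = model$w, b = model$b, W_reg = as.numeric(model$W_reg),
    W_reg_dim = dim(model$W_reg),
    feat_mean = model$feat_mean, feat_sd = model$feat_sd,
    radii = model$radii, classes = model$classes,
    patch_size = model$patch_size, provenance = model$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  j <- jsonlite::fromJSON(path)
  if (is.null(j$format) || j$format != "chipcell-detector-v1") {
    stop(sprintf("%s is not a chipcell detector checkpoint", path), call. = FALSE)
  }
  structure(list(
    w = as.numeric(j$w), b = as.numeric(j$b),
    W_reg = matrix(as.numeric(j$W_reg), j$W_reg_dim[1], j$W_reg_dim[2]),
    feat_mean = as.numeric(j$feat_mean), feat_sd = as.numeric(j$feat_sd),
    radii = as.numeric(j$radii), classes = as.character(j$classes),
    patch_size = as.integer(j$patch_size), provenance = j$provenance
  ), class = "chip_detector")
}
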