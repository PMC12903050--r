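#' chipcell: cell detection in microfluidic trap arrays
#'
#' Synthetic bright-field scene generation, a trainable two-stage
#' region-proposal cell detector, a circular-Hough baseline, bounding-box
#' evaluation, whole-array chamber cropping, and time-lapse killing-assay
#' quantification.
#'
#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic operations in the package go
# through this so that identical seeds give bit-identical results regardless
# of the surrounding session state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)  # x first: pmin/pmax keep its dim

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}

# 1-D Gaussian kernel, truncated at 3 sigma, normalized.
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with edge replication. `img` is a numeric matrix.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  img <- conv_sep_1d(img, k, along = "rows")
  conv_sep_1d(img, k, along = "cols")
}

# Convolve each row/column with kernel k (odd length), replicating edges.
conv_sep_1d <- function(img, k, along = c("rows", "cols")) {
  along <- match.arg(along)
  if (along == "cols") return(t(conv_sep_1d(t(img), k, "rows")))
  half <- (length(k) - 1L) %/% 2L
  n <- nrow(img)
  # pad rows by replication, then sum shifted copies
  idx <- c(rep(1L, half), seq_len(n), rep(n, half))
  pad <- img[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(img))
  for (j in seq_along(k)) {
    out <- out + k[j] * pad[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

# 2-D "same"-size circular cross-correlation via FFT. The kernel is given as a
# full-size matrix already centered at (1,1) wrap-around position, or built by
# embed_kernel(). Used by the Hough accumulator and the blob proposer.
xcorr_fft <- function(img, kern_embedded) {
  F1 <- stats::fft(img)
  F2 <- stats::fft(kern_embedded)
  re <- Re(stats::fft(F1 * Conj(F2), inverse = TRUE)) / length(img)
  re
}

# Embed a small odd-sized kernel into an h x w matrix centered on [1,1] with
# wrap-around, suitable for xcorr_fft.
embed_kernel <- function(kern, h, w) {
  kh <- nrow(kern); kw <- ncol(kern)
  if (kh > h || kw > w) stop("kernel larger than image", call. = FALSE)
  out <- matrix(0, h, w)
  cy <- (kh + 1L) %/% 2L; cx <- (kw + 1L) %/% 2L
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      out[((i - cy) %% h) + 1L, ((j - cx) %% w) + 1L] <- kern[i, j]
    }
  }
  out
}

# Otsu threshold of a numeric vector (256-bin histogram).
otsu_threshold <- function(x, n_bins = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- graphics::hist(x, breaks = seq(r[1], r[2], length.out = n_bins + 1L),
                      plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  total <- sum(counts)
  best <- -Inf; thr <- mids[1]
  wB <- 0; sumB <- 0
  sum_all <- sum(counts * mids)
  for (i in seq_len(n_bins - 1L)) {
    wB <- wB + counts[i]
    if (wB == 0) next
    wF <- total - wB
    if (wF == 0) break
    sumB <- sumB + counts[i] * mids[i]
    mB <- sumB / wB
    mF <- (sum_all - sumB) / wF
    between <- wB * wF * (mB - mF)^2
    if (between > best) {
      best <- between
      thr <- (mids[i] + mids[i + 1L]) / 2
    }
  }
  thr
}

# Strict local maxima of a matrix within a (2k+1)^2 neighborhood, above `thr`.
# Returns a data.frame(row, col, value) sorted by decreasing value.
local_maxima <- function(m, k = 1L, thr = -Inf) {
  h <- nrow(m); w <- ncol(m)
  big <- -Inf
  padded <- matrix(big, h + 2L * k, w + 2L * k)
  padded[k + seq_len(h), k + seq_len(w)] <- m
  is_max <- matrix(TRUE, h, w)
  for (dy in -k:k) {
    for (dx in -k:k) {
      if (dy == 0L && dx == 0L) next
      shifted <- padded[k + dy + seq_len(h), k + dx + seq_len(w)]
      is_max <- is_max & (m >= shifted)
    }
  }
  keep <- which(is_max & (m > thr), arr.ind = TRUE)
  if (nrow(keep) == 0L) {
    return(data.frame(row = integer(), col = integer(), value = numeric()))
  }
  v <- m[keep]
  o <- order(-v, keep[, 1L], keep[, 2L])
  data.frame(row = keep[o, 1L], col = keep[o, 2L], value = v[o])
}

# Sobel gradient magnitude of a matrix.
sobel_magnitude <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv3x3(img, kx)
  gy <- conv3x3(img, t(kx))
  sqrt(gx^2 + gy^2)
}

conv3x3 <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  idx_r <- c(1L, seq_len(h), h)
  idx_c <- c(1L, seq_len(w), w)
  pad <- img[idx_r, idx_c, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in 1:3) {
    for (j in 1:3) {
      if (k[i, j] == 0) next
      out <- out + k[i, j] * pad[(i - 1L) + seq_len(h), (j - 1L) + seq_len(w)]
    }
  }
  out
}
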