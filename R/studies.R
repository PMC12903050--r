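# Per-image content signature, used to enforce pool/test disjointness.
scene_signature <- function(sc) {
  sprintf("%dx%d:%.6f:%d", nrow(sc$pixels), ncol(sc$pixels),
          sum(sc$pixels), nrow(sc$boxes))
}

new_study_result <- function(per_rep, group_var) {
  agg <- do.call(rbind, lapply(split(per_rep, per_rep[[group_var]]), function(d) {
    data.frame(condition = d[[group_var]][1], mean_ap = mean(d$ap),
               sd_ap = stats::sd(d$ap), n = nrow(d))
  }))
  rownames(agg) <- NULL
  structure(list(replicates = per_rep, summary = agg), class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  print(x$summary)
  invisible(x)
}

#' Training-set size study
#'
#' For each requested annotation count, trains `replicates` detectors on
#' random image subsets pooled from `image_pool` (images are drawn until the
#' cumulative annotation count reaches the requested size) and evaluates
#' each on the common held-out `test_set` by average precision. The pool
#' and the test set must be disjoint.
#'
#' @param image_pool List of annotated scenes to draw training sets from.
#' @param sizes Annotation counts to compare (e.g. `c(1, 40, 400)`).
#' @param replicates Models per size (default 5).
#' @param test_set List of annotated scenes, disjoint from the pool.
#' @param config Base [train_config()]; the per-replicate seed is derived
#'   from `seed`.
#' @param seed Study-level RNG seed.
#' @return A `study_result`: per-replicate AP table plus per-size mean/sd.
#' @export
run_training_size_study <- function(image_pool, sizes, replicates = 5L,
                                    test_set, config = train_config(),
                                    seed = 1L) {
  pool_sig <- vapply(image_pool, scene_signature, "")
  test_sig <- vapply(test_set, scene_signature, "")
  if (length(intersect(pool_sig, test_sig)) > 0L) {
    stop("training pool and test set overlap", call. = FALSE)
  }
  n_ann <- vapply(image_pool, function(s) nrow(s$boxes), 1L)
  if (max(sizes) > sum(n_ann)) {
    stop("pool too small for the largest requested training size", call. = FALSE)
  }
  gts <- lapply(test_set, function(s) s$boxes)
  rows <- NULL
  with_seed(seed, {
    for (sz in sizes) {
      for (rep_i in seq_len(replicates)) {
        ord <- sample(length(image_pool))
        cum <- cumsum(n_ann[ord])
        take <- ord[seq_len(which(cum >= sz)[1])]
        cfg <- config
        cfg$seed <- as.integer((as.numeric(seed) * 131 + sz * 17 + rep_i) %% 2147483647)
        fit <- train_detector(image_pool[take], cfg)
        preds <- lapply(seq_along(test_set), function(k)
          infer(fit$model, test_set[[k]]$pixels, image_id = sprintf("test%03d", k)))
        ap <- average_precision(preds, gts)$ap
        rows <- rbind(rows, data.frame(size = sz, replicate = rep_i, ap = ap))
      }
    }
  })
  new_study_result(rows, "size")
}

#' Synthetic annotator variants of a dataset
#'
#' Stands in for independent human annotators: each box is jittered by a
#' uniform offset up to `jitter_px` per edge and dilated/eroded by
#' `dilate_frac` of its size, then clipped to image bounds.
#'
#' @param dataset List of annotated scenes.
#' @param jitter_px Maximum per-edge jitter in pixels.
#' @param dilate_frac Relative size change (positive dilates).
#' @param seed RNG seed.
#' @return The dataset with perturbed boxes.
#' @export
perturb_annotations <- function(dataset, jitter_px = 1, dilate_frac = 0,
                                seed = 1L) {
  with_seed(seed, {
    lapply(dataset, function(sc) {
      b <- sc$boxes
      n <- nrow(b)
      if (n > 0L) {
        w <- b$x_max - b$x_min; h <- b$y_max - b$y_min
        b$x_min <- b$x_min + stats::runif(n, -jitter_px, jitter_px) - dilate_frac * w / 2
        b$x_max <- b$x_max + stats::runif(n, -jitter_px, jitter_px) + dilate_frac * w / 2
        b$y_min <- b$y_min + stats::runif(n, -jitter_px, jitter_px) - dilate_frac * h / 2
        b$y_max <- b$y_max + stats::runif(n, -jitter_px, jitter_px) + dilate_frac * h / 2
        b <- clip_boxes(b, ncol(sc$pixels), nrow(sc$pixels))
      }
      sc$boxes <- b
      sc
    })
  })
}

#' Annotator-variability study
#'
#' Takes two or more labelings of the *same* images (e.g. synthetic
#' annotator variants from [perturb_annotations()]), trains `replicates`
#' models per annotator on random subsets of `n_annotations` labels, and
#' evaluates each on the common `test_set`. Reports per-annotator AP
#' distributions and the between-annotator standard deviation of mean APs.
#'
#' @param annotation_sets Named list (length >= 2) of annotated-scene lists
#'   covering the same images.
#' @param replicates Models per annotator (default 5).
#' @param test_set Held-out annotated scenes.
#' @param n_annotations Annotation budget per trained model (default 40).
#' @param config Base [train_config()].
#' @param seed Study-level RNG seed.
#' @return A `study_result` with `between_annotator_sd` added.
#' @export
run_annotator_study <- function(annotation_sets, replicates = 5L, test_set,
                                n_annotations = 40L, config = train_config(),
                                seed = 1L) {
  if (length(annotation_sets) < 2L) {
    stop("need at least two annotation sets", call. = FALSE)
  }
  if (is.null(names(annotation_sets)) || any(names(annotation_sets) == "")) {
    names(annotation_sets) <- LETTERS[seq_along(annotation_sets)]
  }
  img_sig <- function(set) vapply(set, function(sc)
    sprintf("%dx%d:%.6f", nrow(sc$pixels), ncol(sc$pixels), sum(sc$pixels)), "")
  ref <- img_sig(annotation_sets[[1]])
  for (s in annotation_sets[-1]) {
    if (!identical(img_sig(s), ref)) {
      stop("annotation sets must cover the same images", call. = FALSE)
    }
  }
  gts <- lapply(test_set, function(s) s$boxes)
  rows <- NULL
  with_seed(seed, {
    for (ann in names(annotation_sets)) {
      set <- annotation_sets[[ann]]
      n_ann <- vapply(set, function(s) nrow(s$boxes), 1L)
      for (rep_i in seq_len(replicates)) {
        ord <- sample(length(set))
        cum <- cumsum(n_ann[ord])
        idx <- which(cum >= n_annotations)
        take <- ord[seq_len(if (length(idx)) idx[1] else length(set))]
        cfg <- config
        cfg$seed <- as.integer((as.numeric(seed) * 977 +
                                match(ann, names(annotation_sets)) * 31 +
                                rep_i) %% 2147483647)
        fit <- train_detector(set[take], cfg)
        preds <- lapply(seq_along(test_set), function(k)
          infer(fit$model, test_set[[k]]$pixels, image_id = sprintf("test%03d", k)))
        ap <- average_precision(preds, gts)$ap
        rows <- rbind(rows, data.frame(annotator = ann, replicate = rep_i, ap = ap))
      }
    }
  })
  res <- new_study_result(rows, "annotator")
  res$between_annotator_sd <- stats::sd(res$summary$mean_ap)
  res
}
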