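test_that("count_t0 applies the 0.9 cutoff", {
  d <- detection_set(bounding_boxes(c(0, 20, 40), c(0, 0, 0),
                                    c(10, 30, 50), c(10, 10, 10),
                                    confidence = c(0.95, 0.92, 0.7)))
  expect_equal(count_t0(d), 2L)
  expect_equal(count_t0(detection_set(bounding_boxes())), 0L)
  expect_equal(count_t0(d, conf = 0.5), 3L)
})

test_that("select_constant_count returns exact top-N with effective threshold", {
  d <- detection_set(bounding_boxes(c(0, 20, 40, 60), c(0, 0, 0, 0),
                                    c(10, 30, 50, 70), c(10, 10, 10, 10),
                                    confidence = c(0.95, 0.9, 0.7, 0.6)))
  s <- select_constant_count(d, 3)
  expect_equal(nrow(s$detections), 3L)
  expect_equal(s$effective_threshold, 0.7)
  expect_equal(s$shortfall, 0L)

  expect_equal(nrow(select_constant_count(d, 0)$detections), 0L)

  expect_warning(s2 <- select_constant_count(d, 10), "4 of the requested 10")
  expect_equal(nrow(s2$detections), 4L)
  expect_equal(s2$shortfall, 6L)

  # output size identity over random inputs
  set.seed(3)
  for (i in 1:50) {
    dd <- detection_set(random_boxes(sample(0:8, 1), confidence = TRUE))
    n <- sample(0:10, 1)
    s3 <- suppressWarnings(select_constant_count(dd, n))
    expect_equal(nrow(s3$detections), min(n, nrow(dd)))
  }
})

test_that("roi_mean_fluorescence averages the half-open box", {
  img <- matrix(0.37, 20, 20)
  expect_equal(roi_mean_fluorescence(c(2, 3, 8, 9), img), 0.37)
  img2 <- matrix(0, 4, 4)
  img2[1, 1] <- 10; img2[1, 2] <- 10
  expect_equal(roi_mean_fluorescence(c(0, 0, 2, 2), img2), 5)
  expect_equal(roi_mean_fluorescence(c(0, 0, 20, 20), img), mean(img))
  expect_error(roi_mean_fluorescence(c(0, 0, 25, 10), img), "outside")
})

test_that("bimodal_threshold finds the between-mode minimum", {
  set.seed(2)
  v <- c(rnorm(250, 0.1, 0.05), rnorm(250, 0.9, 0.05))
  thr <- bimodal_threshold(v)
  expect_lt(abs(thr - 0.5), 0.1)  # analytic equal-weight crossing is 0.5

  expect_error(bimodal_threshold(rep(0.5, 20)), "unimodal")
  expect_error(bimodal_threshold(rnorm(5)), "at least 10")

  # outlier beyond the high mode moves the threshold by at most ~1 bin
  v2 <- c(v, 2.5)
  bw <- diff(range(v2)) / 50
  expect_lt(abs(bimodal_threshold(v2) - thr), max(bw, diff(range(v)) / 50) + 1e-9)
})

test_that("bimodal_threshold converges to the analytic crossing at n = 5000", {
  set.seed(14)
  for (i in 1:5) {
    v <- c(rnorm(2500, 0.1, 0.05), rnorm(2500, 0.9, 0.05))
    thr <- bimodal_threshold(v)
    bin_w <- diff(range(v)) / 50
    expect_lte(abs(thr - 0.5), bin_w + 1e-12)  # equal-weight crossing = 0.5
  }
})

test_that("build_trajectories links trapped cells across timepoints", {
  b <- bounding_boxes(c(0, 30), c(0, 0), c(10, 40), c(10, 10),
                      confidence = c(0.95, 0.9))
  frames <- list(detection_set(b), detection_set(b), detection_set(b))
  trajs <- build_trajectories(frames, max_disp_px = 5)
  expect_length(trajs, 2L)
  expect_true(all(vapply(trajs, function(tr) tr$complete, TRUE)))

  # 1 px jitter per frame stays one trajectory
  b2 <- b; b2[, 1:4] <- b2[, 1:4] + 1
  b3 <- b; b3[, 1:4] <- b3[, 1:4] + 2
  trajs2 <- build_trajectories(list(detection_set(b), detection_set(b2),
                                    detection_set(b3)), max_disp_px = 5)
  expect_length(trajs2, 2L)
  expect_true(all(vapply(trajs2, function(tr) length(tr$t) == 3L, TRUE)))

  # a box disappearing at t2 terminates its trajectory, flagged incomplete
  only1 <- detection_set(b[1, , drop = FALSE])
  trajs3 <- build_trajectories(list(detection_set(b), detection_set(b), only1),
                               max_disp_px = 5)
  lens <- sort(vapply(trajs3, function(tr) length(tr$t), 1L))
  expect_equal(lens, c(2L, 3L))
  incomplete <- trajs3[[which(vapply(trajs3, function(tr) !tr$complete, TRUE))]]
  expect_equal(length(incomplete$t), 2L)
})

test_that("survival_curve applies the threshold with absorbing dead state", {
  mk_traj <- function(id, fl) {
    structure(list(id = id, t = seq_along(fl),
                   boxes = bounding_boxes(rep(0, length(fl)), 0,
                                          rep(10, length(fl)), 10),
                   fluor = fl, complete = TRUE), class = "cell_trajectory")
  }
  # all below threshold: live fraction 1 throughout
  res <- survival_curve(list(mk_traj(1, c(0.1, 0.1)), mk_traj(2, c(0.2, 0.1))),
                        threshold = 0.5)
  expect_equal(res$curve$live_fraction, c(1, 1))

  # one cell dips back under threshold: absorbing keeps it dead
  tr <- list(mk_traj(1, c(0.1, 0.9, 0.1)), mk_traj(2, c(0.1, 0.1, 0.1)))
  res2 <- survival_curve(tr, threshold = 0.5, absorbing = TRUE)
  expect_equal(res2$curve$n_live, c(2L, 1L, 1L))
  res3 <- survival_curve(tr, threshold = 0.5, absorbing = FALSE)
  expect_equal(res3$curve$n_live, c(2L, 1L, 2L))

  # threshold above all values: everyone lives
  res4 <- survival_curve(tr, threshold = 2)
  expect_equal(res4$curve$live_fraction, c(1, 1, 1))
})

test_that("run_assay recovers a planted kill schedule from truth boxes", {
  # ground-truth detections (confidence 1) isolate the analysis chain from
  # the detector: recovery should be near-exact
  a <- make_timelapse_assay(scene_spec(n_cells = 12, chamber_type = 1,
                                       cell_diameter_px = c(18, 1.5),
                                       seed = 31),
                            n_frames = 3, kill_schedule = c(0, 0.5, 2 / 3))
  gt_dets <- lapply(1:3, function(t) {
    b <- a$boxes
    b$confidence <- 0.99
    detection_set(b, image_id = sprintf("t%d", t))
  })
  fl <- lapply(a$frames, `[[`, "fluorescence")
  res <- run_assay(gt_dets, fl, conf = 0.9)
  expect_equal(res$n_total, 12L)
  planted <- colSums(a$states == "live") / 12
  expect_true(all(abs(res$curve$live_fraction - planted) <= 0.05 + 1e-9))
  expect_equal(res$effective_thresholds[1], 0.9)
})
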