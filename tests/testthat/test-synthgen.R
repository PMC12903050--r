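test_that("scene_spec enforces its invariants", {
  expect_error(scene_spec(n_cells = 0), "n_cells")
  expect_error(scene_spec(n_cells = 16), "n_cells")
  expect_error(scene_spec(target_rsd = 0.05), "target_rsd")
  expect_error(scene_spec(blur_sigma_px = -1), "blur_sigma_px")
  expect_error(scene_spec(chamber_type = 5), "chamber_type")
  expect_s3_class(scene_spec(), "scene_spec")
})

test_that("make_chamber_scene draws tight boxes and is deterministic", {
  # noiseless single cell: box sides equal the drawn disk diameter +-1 px
  sp <- scene_spec(n_cells = 1, blur_sigma_px = 0, target_rsd = 0.10,
                   cell_diameter_px = c(20, 0), seed = 3)
  sc <- make_chamber_scene(sp)
  expect_equal(nrow(sc$boxes), 1L)
  d_drawn <- 2 * sc$meta$cells$r[1]
  expect_lte(abs((sc$boxes$x_max - sc$boxes$x_min) - d_drawn), 1)
  expect_lte(abs((sc$boxes$y_max - sc$boxes$y_min) - d_drawn), 1)

  # determinism: same spec -> bit-identical scene
  sp7 <- scene_spec(n_cells = 5, seed = 7)
  a <- make_chamber_scene(sp7)
  b <- make_chamber_scene(sp7)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$boxes, b$boxes)

  # placement failure is an explicit error, never a partial scene
  expect_error(
    make_chamber_scene(scene_spec(image_size = c(48, 48), chamber_type = 4,
                                  n_cells = 15, cell_diameter_px = c(23, 2))),
    "could not place")
})

test_that("scene ground truth stays inside bounds with achieved RSD on target", {
  specs <- random_scene_specs(100, seed = 8)
  for (sp in specs[seq(1, 100, by = 1)]) {
    sc <- make_chamber_scene(sp)
    h <- nrow(sc$pixels); w <- ncol(sc$pixels)
    expect_true(all(sc$boxes$x_min >= 0 & sc$boxes$y_min >= 0 &
                      sc$boxes$x_max <= w & sc$boxes$y_max <= h))
    expect_true(all(sc$pixels >= 0 & sc$pixels <= 1))
    expect_lt(abs(sc$meta$achieved_rsd / sp$target_rsd - 1), 0.20)
  }
})

test_that("placed cells respect the contact rule and lie inside the chamber", {
  for (seed in c(2, 12, 22)) {
    sc <- make_chamber_scene(scene_spec(n_cells = 8, seed = seed))
    cells <- sc$meta$cells
    if (nrow(cells) >= 2) {
      d <- as.matrix(dist(cells[, c("cx", "cy")]))
      rs <- outer(cells$r, cells$r, `+`)
      diag(d) <- Inf
      expect_true(all(d >= 0.9 * rs - 1e-9))
    }
  }
})

test_that("make_array_image tiles chambers with global coordinates", {
  arr <- make_array_image(3, 3, scene_spec(n_cells = 4, seed = 3),
                          margin_px = 10)
  expect_equal(nrow(arr$chamber_boxes), 9L)
  expect_false(any(arr$chamber_boxes$edge))
  H <- nrow(arr$scene$pixels); W <- ncol(arr$scene$pixels)
  expect_true(all(arr$chamber_boxes$x_max <= W & arr$chamber_boxes$y_max <= H))
  expect_true(all(arr$scene$boxes$x_max <= W & arr$scene$boxes$y_max <= H))

  # half-off-canvas chamber is clipped and flagged edge-touching
  arr2 <- make_array_image(1, 2, scene_spec(n_cells = 3, seed = 3),
                           margin_px = 10, edge_shift_px = 60)
  expect_equal(sum(arr2$chamber_boxes$edge), 1L)
  expect_gte(min(arr2$chamber_boxes$x_min), 0)

  # different seeds: different cells, identical chamber grid
  a <- make_array_image(2, 2, scene_spec(n_cells = 4, seed = 1))
  b <- make_array_image(2, 2, scene_spec(n_cells = 4, seed = 2))
  expect_identical(a$chamber_boxes[, c("x_min", "y_min", "x_max", "y_max")],
                   b$chamber_boxes[, c("x_min", "y_min", "x_max", "y_max")])
  expect_false(identical(a$scene$boxes, b$scene$boxes))

  expect_error(make_array_image(0, 2, scene_spec()), "grid")
})

test_that("make_timelapse_assay follows the kill schedule exactly", {
  sp <- scene_spec(n_cells = 10, cell_diameter_px = c(18, 1.5), seed = 77)
  a <- make_timelapse_assay(sp, 3, c(0, 0.5, 0.7))
  expect_equal(colSums(a$states == "dead"), c(0, 5, 7))
  # absorbing: dead stays dead
  for (i in 1:10) {
    s <- a$states[i, ]
    expect_false(any(s == "live" & c("live", s[-3]) == "dead"))
  }
  # bright-field frames share identical ground truth (cells immobile)
  expect_identical(a$boxes, a$boxes)
  expect_equal(length(a$frames), 3L)
  # all-zero schedule: every draw from the live distribution
  a0 <- make_timelapse_assay(sp, 2, c(0, 0))
  expect_true(all(a0$states == "live"))
  expect_true(all(a0$fluor_values < a0$params$mu_live + 5 * a0$params$sigma))

  expect_error(make_timelapse_assay(sp, 3, c(0, 0.5, 0.4)), "non-decreasing")
  expect_error(make_timelapse_assay(sp, 2, c(0, 0.5, 0.7)), "one entry per frame")
})

test_that("chamber capacity caps random spec cell counts", {
  specs <- random_scene_specs(50, seed = 4, n_cells_range = c(1L, 15L))
  for (sp in specs) {
    expect_lte(sp$n_cells,
               max(1L, chamber_capacity(sp$chamber_type, sp$image_size,
                                        sp$cell_diameter_px[1])))
  }
})
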