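test_that("VOC coordinates convert between 1-based inclusive and half-open", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    "<annotation><filename>im.pgm</filename>",
    "<size><width>20</width><height>20</height><depth>1</depth></size>",
    "<object><name>cell</name><bndbox>",
    "<xmin>1</xmin><ymin>1</ymin><xmax>10</xmax><ymax>10</ymax>",
    "</bndbox></object></annotation>"), f)
  ann <- read_voc(f)
  expect_equal(as.numeric(ann$boxes[1, 1:4]), c(0, 0, 10, 10))
  expect_equal(ann$boxes$label, "cell")
})

test_that("read_voc rejects malformed files with descriptive errors", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<annotation><object></object>", f)
  expect_error(read_voc(f), "malformed")

  writeLines(c("<annotation><filename>x</filename>",
               "<object><name>cell</name><bndbox>",
               "<xmin>1</xmin><ymin>1</ymin><xmax>5</xmax><ymax>5</ymax>",
               "</bndbox></object></annotation>"), f)
  expect_error(read_voc(f), "<size>")

  # degenerate box: xmax <= xmin
  writeLines(c("<annotation><filename>x</filename>",
               "<size><width>20</width><height>20</height></size>",
               "<object><name>cell</name><bndbox>",
               "<xmin>5</xmin><ymin>1</ymin><xmax>5</xmax><ymax>6</ymax>",
               "</bndbox></object></annotation>"), f)
  expect_error(read_voc(f), "degenerate")

  # box outside declared image size names the offender
  writeLines(c("<annotation><filename>x</filename>",
               "<size><width>20</width><height>20</height></size>",
               "<object><name>cell</name><bndbox>",
               "<xmin>1</xmin><ymin>1</ymin><xmax>25</xmax><ymax>6</ymax>",
               "</bndbox></object></annotation>"), f)
  expect_error(read_voc(f), "outside")

  expect_error(read_voc("no/such/file.xml"), "not found")
})

test_that("VOC write -> read -> write round trip is byte-stable", {
  set.seed(10)
  for (i in 1:10) {
    boxes <- random_boxes(sample(0:8, 1), w = 200, h = 100)
    f1 <- withr::local_tempfile(fileext = ".xml")
    f2 <- withr::local_tempfile(fileext = ".xml")
    write_voc("img.pgm", boxes, c(100, 200), f1)
    back <- read_voc(f1)
    expect_equal(as.matrix(back$boxes[, 1:4]), as.matrix(boxes[, 1:4]),
                 ignore_attr = TRUE)
    write_voc(back$image_ref, back$boxes, back$size, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
  # empty box list is valid XML with zero objects
  f <- withr::local_tempfile(fileext = ".xml")
  write_voc("img.pgm", bounding_boxes(), c(50, 50), f)
  expect_equal(nrow(read_voc(f)$boxes), 0L)
})

test_that("non-integer coordinates are rounded half-up on VOC write", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_voc("img.pgm", bounding_boxes(0.5, 0.4, 10.5, 9.6), c(50, 50), f)
  back <- read_voc(f)
  # xmin 0.5+1 = 1.5 -> 2 -> internal 1; xmax 10.5 -> 11
  expect_equal(as.numeric(back$boxes[1, 1:4]), c(1, 0, 11, 10))
})

test_that("inference CSV has the exact schema and round trips", {
  d <- detection_set(
    bounding_boxes(c(1, 5), c(2, 6), c(11, 15), c(12, 16),
                   confidence = c(0.5, 0.95)),
    image_id = "imA", model = "m")
  f <- withr::local_tempfile(fileext = ".csv")
  write_inferences_csv(d, f)
  raw <- utils::read.csv(f)
  expect_identical(names(raw), c("image_id", "x_min", "y_min", "x_max",
                                 "y_max", "label", "confidence"))
  expect_equal(raw$confidence, c(0.95, 0.5))  # descending confidence
  back <- read_inferences_csv(f)
  expect_equal(det_frame(back[["imA"]]), det_frame(d))

  # zero detections -> header-only file
  write_inferences_csv(detection_set(bounding_boxes(), image_id = "e"), f)
  expect_equal(nrow(utils::read.csv(f)), 0L)
  expect_error(read_inferences_csv(f), NA)
})

test_that("inference CSV round trips 100 random detection sets", {
  set.seed(11)
  f <- withr::local_tempfile(fileext = ".csv")
  sets <- lapply(1:100, function(i)
    detection_set(random_boxes(sample(1:6, 1), confidence = TRUE),
                  image_id = sprintf("im%03d", i)))
  write_inferences_csv(sets, f)
  back <- read_inferences_csv(f)
  expect_equal(length(back), 100L)
  for (i in seq_along(sets)) {
    expect_equal(det_frame(back[[attr(sets[[i]], "image_id")]]),
                 det_frame(sets[[i]]))
  }
})

test_that("COCO JSON import maps [x, y, w, h] onto half-open boxes", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    images = data.frame(id = c(1, 2), file_name = c("a.png", "b.png")),
    annotations = data.frame(id = 1:3, image_id = c(1, 1, 2),
                             category_id = c(1, 1, 1),
                             bbox = I(list(c(0, 0, 10, 10), c(5, 5, 4, 6),
                                           c(2, 3, 7, 7)))),
    categories = data.frame(id = 1, name = "cell")), f,
    auto_unbox = TRUE, digits = NA)
  sets <- read_coco(f)
  expect_equal(names(sets), c("a.png", "b.png"))
  expect_equal(nrow(sets[["a.png"]]), 2L)
  expect_equal(as.numeric(sets[["a.png"]][2, 1:4]), c(5, 5, 9, 11))
  expect_equal(sets[["a.png"]]$label, c("cell", "cell"))
})

test_that("PGM images round trip at 16-bit depth", {
  sc <- make_chamber_scene(scene_spec(n_cells = 3, seed = 5))
  f <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(sc$pixels, f)
  back <- read_pgm(f)
  expect_equal(dim(back), dim(sc$pixels))
  expect_lt(max(abs(back - sc$pixels)), 1 / 65535)
  expect_error(write_pgm(sc$pixels * 2, f), "\\[0, 1\\]")
})
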