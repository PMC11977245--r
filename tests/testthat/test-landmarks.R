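test_that("denormalization maps unit coordinates onto the pixel raster", {
  raw <- list(`14` = c(0.5, 0.5), `15` = c(0, 0), `16` = c(1, 1),
              `17` = c(0.5, 0.9), `84` = c(0.1, 0.5), `87` = c(0.9, 0.5),
              `314` = c(0.2, 0.5), `317` = c(0.8, 0.5))
  lm <- denormalize_landmarks(raw, 200, 100)
  expect_equal(unname(lm$points["14", ]), c(100, 50))
  expect_equal(unname(lm$points["15", ]), c(0, 0))
  expect_equal(unname(lm$points["16", ]), c(200, 100))

  expect_error(denormalize_landmarks(raw[names(raw) != "317"], 200, 100),
               "317")
  bad <- raw; bad$`14` <- c(1.2, 0.5)
  expect_error(denormalize_landmarks(bad, 200, 100), "\\[0, 1\\]")
})

test_that("landmark sets validate the required indices and bounds", {
  expect_error(make_lip_landmarks(10, 10, 40, 20, 30, 30), "bounds")
  lm <- make_lip_landmarks(10, 10, 40, 20, 100, 60)
  expect_s3_class(lm, "landmark_set")
  pts <- lm$points[rownames(lm$points) != "317", ]
  expect_error(landmark_set(pts, 100, 60), "317")
})

test_that("target rectangle uses the max x-span and midpoint y-difference", {
  # spans: |84-87| = 40, |314-317| = 32 -> width 40
  lm <- make_lip_landmarks(20, 15, 40, 22, 120, 80)
  roi <- extract_target_region(lm)
  expect_equal(roi$width, 40)
  expect_equal(roi$height, 22)
  expect_equal(roi$x0, 20)
  expect_equal(roi$y0, 15)

  # hand-built asymmetric spans: 84/87 span 10, 314/317 span 15
  pts <- rbind(`14` = c(30, 100), `15` = c(30, 104),
               `16` = c(30, 120), `17` = c(30, 124),
               `84` = c(10, 110), `87` = c(20, 110),
               `314` = c(30, 110), `317` = c(45, 110))
  lm2 <- landmark_set(pts, 200, 200)
  roi2 <- extract_target_region(lm2)
  expect_equal(roi2$width, 15)
  expect_equal(roi2$height, 20)  # |102 - 122|
})

test_that("degenerate landmark geometry is rejected", {
  pts <- rbind(`14` = c(50, 10), `15` = c(50, 14), `16` = c(50, 30),
               `17` = c(50, 34), `84` = c(50, 20), `87` = c(50, 20),
               `314` = c(50, 20), `317` = c(50, 20))
  expect_error(extract_target_region(landmark_set(pts, 100, 100)),
               "degenerate ROI")
})

test_that("rectangle extraction is translation-equivariant", {
  base <- make_lip_landmarks(20, 15, 40, 22, 400, 400)
  roi <- extract_target_region(base)
  for (shift in list(c(5, 0), c(0, 7), c(13, 11))) {
    pts <- base$points
    pts[, "x"] <- pts[, "x"] + shift[1]
    pts[, "y"] <- pts[, "y"] + shift[2]
    roi2 <- extract_target_region(landmark_set(pts, 400, 400))
    expect_equal(roi2$x0, roi$x0 + shift[1])
    expect_equal(roi2$y0, roi$y0 + shift[2])
    expect_equal(roi2$width, roi$width)
    expect_equal(roi2$height, roi$height)
  }
})

test_that("rectangles extending past the image are clipped with a warning", {
  # in-bounds landmarks whose asymmetric spans centre the rectangle so
  # that it would overhang the right image edge
  pts <- rbind(`14` = c(25, 8), `15` = c(25, 12),
               `16` = c(25, 38), `17` = c(25, 42),
               `84` = c(0, 25), `87` = c(48, 25),
               `314` = c(40, 25), `317` = c(50, 25))
  lm <- landmark_set(pts, 50, 60)
  expect_warning(roi <- extract_target_region(lm), "clipped")
  expect_lte(roi$x0 + roi$width, 50)
  expect_equal(roi$height, 30)
})

test_that("cropping honours the half-open pixel convention", {
  img <- array(0, c(100, 100, 3))
  img[11, 11, ] <- 77  # 0-based (10, 10)
  full <- crop_roi(img, lip_roi(0, 0, 100, 100))
  expect_identical(full, img)
  sub <- crop_roi(img, lip_roi(10, 10, 5, 5))
  expect_equal(dim(sub), c(5, 5, 3))
  expect_equal(sub[1, 1, 1], 77)
  expect_error(lip_roi(0, 0, 0, 5), "degenerate")
  expect_error(crop_roi(img, lip_roi(98, 98, 5, 5)), "outside")
})

test_that("landmark files round-trip through JSON in both coordinate modes", {
  lm <- make_lip_landmarks(20, 15, 40, 22, 120, 80)
  roi <- extract_target_region(lm)
  for (norm in c(FALSE, TRUE)) {
    path <- withr::local_tempfile(fileext = ".json")
    write_landmarks(lm, path, normalized = norm)
    lm2 <- read_landmarks(path)
    expect_equal(lm2$points, lm$points, tolerance = 1e-12)
    roi2 <- extract_target_region(lm2)
    expect_equal(unclass(roi2), unclass(roi))
  }
})
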