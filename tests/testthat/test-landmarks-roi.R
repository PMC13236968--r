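make_lms <- function(pts, frame = "original", width = 100, height = 100) {
  landmark_set(pts, frame = frame, width = width, height = height)
}

test_that("resize_for_detection scales width to the target and reports s", {
  img <- array(runif(30 * 3000 * 3, 0, 255), c(30, 3000, 3))
  out <- resize_for_detection(img, target_width = 600)
  expect_equal(out$scale, 5)
  expect_equal(dim(out$raster)[2], 600)

  img2 <- array(runif(20 * 600 * 3, 0, 255), c(20, 600, 3))
  out2 <- resize_for_detection(img2, 600)
  expect_identical(out2$raster, img2)
  expect_equal(out2$scale, 1)

  # no upscaling of narrow images
  out3 <- resize_for_detection(img2[, 1:300, ], 600)
  expect_equal(out3$scale, 1)
})

test_that("resized-frame corner coordinates round-trip within 1 px", {
  img <- array(runif(200 * 601 * 3, 0, 255), c(200, 601, 3))
  out <- resize_for_detection(img, 600)
  s <- out$scale
  expect_equal(s, 601 / 600)
  expect_equal(dim(out$raster)[1], round(200 / s))
  corners <- rbind(c(0, 0), c(600, 0), c(0, dim(out$raster)[1]))
  back <- corners * s / s
  expect_true(all(abs(back - corners) < 1))
})

test_that("rescale_points maps resized coordinates to the original frame", {
  lms <- make_lms(rbind(c(100, 50), c(119.8, 33.3)), frame = "resized")
  out <- rescale_points(lms, 5)
  expect_equal(unname(out$points[1, ]), c(500, 250))
  expect_equal(out$frame, "original")
  out2 <- rescale_points(lms, 2.5)
  expect_equal(unname(out2$points[2, ]), c(299.5, 83.25))
  expect_equal(rescale_points(lms, 1)$points, lms$points)
  expect_error(rescale_points(out, 2), "resized")
  expect_error(rescale_points(lms, 0), "positive")
})

test_that("extract_roi applies margin, scaling and integer rounding", {
  topo <- list(periocular = list(1:2, 3:4), eyebrow = list(1:2, 3:4))
  img <- array(0, c(100, 100, 3))
  pts <- rbind(c(10, 20), c(30, 40), c(60, 20), c(80, 40))
  roi <- extract_roi(make_lms(pts), 1, margin = 5, img, topo)
  expect_equal(c(roi$box$x0, roi$box$y0, roi$box$x1, roi$box$y1),
               c(5, 15, 35, 45))
  expect_equal(dim(roi$raster)[1:2], c(30, 30))
  expect_equal(roi$box$origin, c(5L, 15L))

  # m = 0: tight bounding box
  roi0 <- extract_roi(make_lms(pts), 1, margin = 0, img, topo)
  expect_equal(c(roi0$box$x0, roi0$box$y0, roi0$box$x1, roi0$box$y1),
               c(10, 20, 30, 40))

  # resized-frame landmarks with s = 2 scale the expanded bounds
  lms_r <- make_lms(pts, frame = "resized", width = 50, height = 50)
  roi2 <- extract_roi(lms_r, 1, margin = 5, img, topo)
  expect_equal(c(roi2$box$x0, roi2$box$y0, roi2$box$x1, roi2$box$y1),
               c(10, 30, 70, 90))
})

test_that("extract_roi fails loudly on degenerate inputs", {
  topo <- list(periocular = list(1:2, 3:4), eyebrow = list(1:2, 3:4))
  img <- array(0, c(100, 100, 3))
  same <- make_lms(rbind(c(10, 10), c(10, 10), c(50, 50), c(60, 60)))
  expect_error(extract_roi(same, 1, 5, img, topo), "degenerate")
  far <- make_lms(rbind(c(500, 500), c(600, 600), c(1, 1), c(2, 2)),
                  width = 1000, height = 1000)
  expect_error(extract_roi(far, 1, 5, img, topo), "outside")
  expect_error(extract_roi(make_lms(rbind(c(1, 1), c(2, 2), c(3, 3), c(4, 4))),
                           1, margin = -1, img, topo), "margin")
})

test_that("ROI local coordinates round-trip exactly", {
  box <- roi_box(10, 30, 70, 90)
  expect_equal(unname(to_local(c(70, 90), box)[1, ]), c(60, 60))
  box0 <- roi_box(0, 0, 10, 10)
  p <- cbind(runif(20, 0, 9), runif(20, 0, 9))
  expect_equal(to_local(p, box0), p, ignore_attr = TRUE)
  expect_identical(from_local(to_local(p, box), box), p)
})

test_that("combined_roi equals the brute-force box over the union", {
  topo <- list(periocular = list(1:3, 4:6), eyebrow = list(1:3, 4:6))
  img <- array(0, c(200, 200, 3))
  set.seed(41)
  for (rep in 1:20) {
    pts <- cbind(runif(6, 20, 170), runif(6, 20, 170))
    m <- sample(0:8, 1)
    comb <- combined_roi(make_lms(pts, width = 200, height = 200), m, img, topo)
    expect_equal(comb$box$x0, max(0, floor(min(pts[, 1]) - m)))
    expect_equal(comb$box$x1, min(200, ceiling(max(pts[, 1]) + m)))
    expect_equal(comb$box$y0, max(0, floor(min(pts[, 2]) - m)))
    expect_equal(comb$box$y1, min(200, ceiling(max(pts[, 2]) + m)))
    # containment of the per-eye boxes at equal margin
    for (eye in 1:2) {
      b <- extract_roi(make_lms(pts, width = 200, height = 200),
                       eye, m, img, topo)$box
      expect_true(b$x0 >= comb$box$x0 && b$x1 <= comb$box$x1 &&
                    b$y0 >= comb$box$y0 && b$y1 <= comb$box$y1)
    }
  }
})

test_that("every landmark lies inside its margin-expanded ROI box", {
  topo <- list(periocular = list(1:5, 6:10), eyebrow = list(1:5, 6:10))
  img <- array(0, c(300, 300, 3))
  set.seed(7)
  for (rep in 1:10) {
    pts <- cbind(runif(10, 50, 250), runif(10, 50, 250))
    lms <- make_lms(pts, width = 300, height = 300)
    for (eye in 1:2) {
      box <- extract_roi(lms, eye, 10, img, topo)$box
      sub <- pts[topo$periocular[[eye]], ]
      expect_true(all(sub[, 1] >= box$x0 & sub[, 1] <= box$x1 &
                        sub[, 2] >= box$y0 & sub[, 2] <= box$y1))
    }
  }
})

test_that("eyebrow_geometry returns the vertical extent of the brow polygon", {
  topo <- list(periocular = list(1:4, 5:8), eyebrow = list(1:4, 5:8))
  pts <- rbind(c(10, 100), c(20, 140), c(30, 120), c(40, 100),
               c(60, 100), c(70, 110), c(80, 105), c(90, 100))
  g <- eyebrow_geometry(make_lms(pts, width = 200, height = 200), 1, topo)
  expect_equal(g$height, 40)
  flat <- rbind(c(10, 100), c(20, 100), c(30, 100), c(40, 100))
  expect_error(
    eyebrow_geometry(make_lms(flat, width = 200, height = 200), 1,
                     list(periocular = list(1:4, 1:4),
                          eyebrow = list(1:4, 1:4))),
    "degenerate")
})

test_that("landmark JSON sidecars round-trip", {
  lms <- make_lms(rbind(c(10.5, 20.25), c(30, 40)), width = 640, height = 480)
  f <- tempfile(fileext = ".json")
  write_landmarks(lms, f)
  back <- read_landmarks(f)
  expect_equal(back$points, lms$points)
  expect_equal(back$frame, "original")
  expect_equal(back$width, 640)
})
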