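tri_pts <- rbind(c(4, 4), c(16, 4), c(10, 12))

test_that("expand_landmarks shifts upper points up and lower points down", {
  poly <- rbind(c(50, 100), c(60, 100), c(50, 140), c(60, 140))
  out <- expand_landmarks(poly, 30)
  expect_equal(out[1, 2], 70)   # upper: y - delta
  expect_equal(out[3, 2], 170)  # lower: y + delta
  expect_equal(out[, 1], poly[, 1])
  expect_equal(expand_landmarks(poly, 0), poly)
  expect_error(expand_landmarks(poly[1:2, ], 5), "3 points")
  expect_error(expand_landmarks(poly, -1), ">= 0")
})

test_that("make_trimap derives delta as 30% of the eyebrow height", {
  poly <- rbind(c(10, 10), c(40, 5), c(70, 10), c(10, 40), c(70, 40))
  tm <- make_trimap(poly, h = 100, shape = c(120, 90))
  expect_equal(tm$delta, 30)
})

test_that("hull_and_dilate fills the convex hull of the points", {
  tm <- hull_and_dilate(tri_pts, 0, c(20, 24))
  # oracle: half-plane point-in-triangle test on the pixel grid
  inside <- function(x, y) {
    s1 <- (16 - 4) * (y - 4) - (4 - 4) * (x - 4)
    s2 <- (10 - 16) * (y - 4) - (12 - 4) * (x - 16)
    s3 <- (4 - 10) * (y - 12) - (4 - 12) * (x - 10)
    (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
  }
  for (x in 0:23) for (y in 0:19)
    expect_equal(tm$mask[y + 1, x + 1] == 128, inside(x, y))
})

test_that("dilation grows the unknown region monotonically", {
  sq <- rbind(c(8, 8), c(20, 8), c(20, 16), c(8, 16))
  areas <- sapply(c(0, 2, 4, 6), function(r)
    sum(hull_and_dilate(sq, r, c(30, 34))$mask == 128))
  expect_equal(areas[1], 13 * 9)
  expect_true(all(diff(areas) > 0))
  # containment, not just area growth
  a <- hull_and_dilate(sq, 2, c(30, 34))$mask == 128
  b <- hull_and_dilate(sq, 4, c(30, 34))$mask == 128
  expect_true(all(b[a]))
})

test_that("unknown region is monotone in the expansion offset delta", {
  # paired upper/lower columns, as in a face-mesh eyebrow contour: every
  # vertex stays inside its vertically expanded segment, so the hull grows
  poly <- rbind(c(10, 20), c(30, 14), c(50, 20), c(10, 30), c(30, 28),
                c(50, 30))
  masks <- lapply(c(0, 4, 9), function(d)
    hull_and_dilate(expand_landmarks(poly, d), 0, c(60, 70))$mask == 128)
  expect_true(all(masks[[2]][masks[[1]]]))
  expect_true(all(masks[[3]][masks[[2]]]))
})

test_that("hull vertices agree with the brute-force O(n^3) hull", {
  set.seed(12)
  for (rep in 1:15) {
    pts <- cbind(runif(10, 0, 40), runif(10, 0, 30))
    mine <- pts[sort(grDevices::chull(pts)), , drop = FALSE]
    oracle <- bf_hull_vertices(pts)
    expect_equal(mine[order(mine[, 1], mine[, 2]), ],
                 oracle[order(oracle[, 1], oracle[, 2]), ],
                 ignore_attr = TRUE)
    # hull of hull is idempotent
    hh <- mine[grDevices::chull(mine), , drop = FALSE]
    expect_equal(nrow(hh), nrow(mine))
  }
})

test_that("collinear point sets are rejected", {
  line <- cbind(1:5, 2 * (1:5))
  expect_error(hull_and_dilate(line, 0, c(20, 20)), "collinear|degenerate")
})

test_that("propagate_trimap warps labels without inventing new ones", {
  tm <- hull_and_dilate(tri_pts, 2, c(20, 24))
  id <- propagate_trimap(tm, diag(3))
  expect_equal(id$mask, tm$mask)
  expect_equal(id$provenance, "propagated")

  Ht <- diag(3); Ht[1, 3] <- 5
  tr <- propagate_trimap(tm, Ht)
  expect_equal(tr$mask[, 6:24], tm$mask[, 1:19])
  expect_true(all(tr$mask[, 1:5] == 0))

  Hr <- rbind(c(cos(0.2), -sin(0.2), 3), c(sin(0.2), cos(0.2), -1), c(1e-4, 0, 1))
  warped <- propagate_trimap(tm, Hr, target_shape = c(30, 30))
  expect_true(all(warped$mask %in% c(0, 128, 255)))
  # centroid of the warped unknown region tracks the transformed centroid
  idx <- which(warped$mask == 128, arr.ind = TRUE)
  w_cen <- c(mean(idx[, 2] - 1), mean(idx[, 1] - 1))
  idx0 <- which(tm$mask == 128, arr.ind = TRUE)
  t_cen <- apply_homography(Hr, cbind(mean(idx0[, 2] - 1), mean(idx0[, 1] - 1)))
  expect_lt(sqrt(sum((w_cen - t_cen)^2)), 1)

  expect_error(propagate_trimap(tm, matrix(0, 3, 3)), "singular")
})

test_that("trimap PNG round trip is bit-exact", {
  tm <- hull_and_dilate(tri_pts, 3, c(20, 24))
  f <- tempfile(fileext = ".png")
  write_trimap(tm, f)
  back <- read_trimap(f)
  expect_identical(back$mask, tm$mask)
  expect_true(all(back$mask %in% c(0, 128, 255)))
})

test_that("trimap constructor validates labels", {
  expect_error(trimap(matrix(c(0, 1, 128, 255), 2, 2)), "labels")
  m <- matrix(0, 4, 4); m[2, 2] <- 128
  expect_s3_class(trimap(m), "trimap")
})
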