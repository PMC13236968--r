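unit_square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

test_that("estimate_homography recovers exact transforms", {
  H <- estimate_homography(unit_square, unit_square)
  expect_equal(H, diag(3), tolerance = 1e-9, ignore_attr = TRUE)

  shifted <- sweep(unit_square, 2, c(7, -3), "+")
  Ht <- estimate_homography(unit_square, shifted)
  expect_equal(Ht[1, 3], 7, tolerance = 1e-9)
  expect_equal(Ht[2, 3], -3, tolerance = 1e-9)
  expect_equal(Ht[c(2, 3, 4, 6)], rep(0, 4), tolerance = 1e-9)
  expect_equal(Ht[3, 3], 1)
})

test_that("estimate_homography rejects deficient configurations", {
  expect_error(estimate_homography(unit_square[1:3, ], unit_square[1:3, ]),
               "N >= 4")
  line <- cbind(1:5, 2 * (1:5))
  expect_error(estimate_homography(line, line), "degenerate")
})

test_that("consensus sampling survives 20% gross outliers", {
  set.seed(31)
  H_true <- rbind(c(0.98, 0.05, 12), c(-0.04, 1.03, -8), c(2e-5, -1e-5, 1))
  src <- cbind(runif(20, 0, 150), runif(20, 0, 100))
  dst <- apply_homography(H_true, src)
  bad <- 1:4
  dst[bad, ] <- dst[bad, ] + matrix(runif(8, 30, 60), 4, 2)
  Hr <- estimate_homography(src, dst, robust = TRUE)
  expect_lt(rmse_reprojection(src[-bad, ], dst[-bad, ], Hr), 0.5)
  expect_true(all(attr(Hr, "inliers") %in% setdiff(1:20, bad)))
})

test_that("rmse_reprojection equals the brute-force definition", {
  expect_equal(rmse_reprojection(unit_square, unit_square, diag(3)), 0)
  H <- diag(3)
  expect_equal(rmse_reprojection(rbind(c(0, 0)), rbind(c(3, 4)), H), 5)
  set.seed(8)
  src <- cbind(runif(15, 0, 50), runif(15, 0, 50))
  dst <- src + matrix(rnorm(30), 15, 2)
  manual <- sqrt(mean(rowSums((dst - src)^2)))
  expect_equal(rmse_reprojection(src, dst, diag(3)), manual)
})

test_that("warp_image handles identity, translation and inversion", {
  set.seed(9)
  img <- array(runif(40 * 50 * 3, 0, 255), c(40, 50, 3))
  expect_identical(warp_image(img, diag(3)), img)

  m <- matrix(0, 20, 20); m[5:8, 5:8] <- 1
  Ht <- diag(3); Ht[1, 3] <- 5; Ht[2, 3] <- 3
  wm <- warp_image(m, Ht, interpolation = "nearest")
  expect_equal(wm[8:11, 10:13], m[5:8, 5:8])
  expect_equal(sum(wm), sum(m))

  # smooth raster round trip: small mean error away from borders
  x <- seq(0, 4, length.out = 60)
  smooth <- 120 + 60 * outer(sin(x), cos(x))
  Hr <- rbind(c(cos(0.1), -sin(0.1), 4), c(sin(0.1), cos(0.1), -2), c(0, 0, 1))
  there <- warp_image(smooth, Hr)
  back <- warp_image(there, solve(Hr))
  core <- 15:45
  expect_lt(mean(abs(back[core, core] - smooth[core, core])), 2)

  expect_error(warp_image(m, matrix(0, 3, 3)), "singular")
})

test_that("identical images register to the identity with near-zero error", {
  fx <- roi_fixture()
  lm <- to_local(fx$landmarks$points[1:18, ], fx$box)
  chain <- register_two_stage(fx$raster, fx$raster, lm, lm)
  expect_equal(chain$H1, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(chain$rmse_coarse, 1e-6)
  expect_false(chain$fine_fallback)
  expect_lt(chain$rmse_fine, 0.5)
  expect_equal(chain$registered, fx$raster, tolerance = 0.02)
})

test_that("H_total composition matches sequential warps for integer shifts", {
  m <- matrix(0, 30, 30); m[10:14, 8:12] <- 1
  H1 <- diag(3); H1[1, 3] <- 3
  H2 <- diag(3); H2[2, 3] <- 4
  seq_warp <- warp_image(warp_image(m, H1, interpolation = "nearest"),
                         H2, interpolation = "nearest")
  one_warp <- warp_image(m, H2 %*% H1, interpolation = "nearest")
  expect_identical(seq_warp, one_warp)
})

test_that("feature matcher finds mutual correspondences on a textured pair", {
  fx <- roi_fixture()
  Ht <- diag(3); Ht[1, 3] <- 4; Ht[2, 3] <- -3
  moved <- warp_image(fx$raster, Ht, interpolation = "bilinear")
  m <- detect_and_match(moved, fx$raster)
  expect_gte(nrow(m$src), 10)
  proj <- apply_homography(Ht, m$dst)  # dst (original) -> moved frame
  err <- sqrt(rowSums((proj - m$src)^2))
  expect_gt(mean(err < 1.5), 0.8)
})
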