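test_that("binarize uses a strict threshold on the 8-bit map", {
  g <- matrix(c(0, 1, 2, 255), 2, 2, byrow = TRUE)
  expect_equal(binarize(g, 1), matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE))
  expect_true(all(binarize(g, 255) == 0))
  expect_error(binarize(g, 300), "tau")

  set.seed(13)
  g2 <- matrix(sample(0:20, 400, TRUE), 20, 20)
  counts <- sapply(1:10, function(tau) sum(binarize(g2, tau)))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts, sapply(1:10, function(tau) sum(g2 > tau)))
})

test_that("retention parameters scale with the eyebrow height", {
  p <- retention_params(100)
  expect_equal(p$tau_dist, 50)
  expect_equal(p$tau_area, 100)
  expect_equal(p$kernel_open, 5)
  expect_equal(p$kernel_dilate, 7)
  expect_equal(retention_params(10)$kernel_open, 1)
  expect_error(retention_params(0), "> 0")
})

test_that("morphological refinement suppresses salt and keeps solid shapes", {
  m <- matrix(0, 40, 40)
  m[20, 20] <- 1                       # isolated salt pixel
  m[5:15, 5:15] <- 1                   # solid block
  p <- retention_params(100)           # kernels 5 and 7
  out <- refine_morphology(m, p)
  expect_equal(out[20, 20], 0)
  expect_true(all(out[7:13, 7:13] == 1))
  # containment chain: opened-dilated mask contains nothing outside the
  # dilation of the input
  dil_only <- browquant:::ebi_dilate(m, p$kernel_dilate)
  expect_true(all(out <= dil_only))
})

test_that("connected components use 8-connectivity with deterministic labels", {
  m <- matrix(0, 3, 3); m[1, 1] <- 1; m[2, 2] <- 1
  cc <- connected_components(m)
  expect_equal(nrow(cc$table), 1)
  expect_equal(cc$table$area, 2)

  empty <- connected_components(matrix(0, 4, 4))
  expect_equal(nrow(empty$table), 0)

  m2 <- matrix(0, 5, 7)
  m2[1, 6] <- 1; m2[4:5, 2:3] <- 1
  cc2 <- connected_components(m2)
  # row-major first pixel: the single pixel in row 1 gets label 1
  expect_equal(cc2$table$area[1], 1)
  expect_equal(cc2$table$centroid_x[1], 5)
  expect_equal(cc2$table$centroid_y[1], 0)
  expect_equal(cc2$table$area[2], 4)
  expect_equal(cc2$table$centroid_x[2], 1.5)
  expect_equal(cc2$table$centroid_y[2], 3.5)
})

test_that("labeling matches the flood-fill oracle on random sprinkles", {
  set.seed(14)
  for (rep in 1:12) {
    m <- matrix(rbinom(30 * 25, 1, runif(1, 0.15, 0.5)), 30, 25)
    cc <- connected_components(m)
    oracle <- bf_flood_label(m)
    expect_identical(cc$labels, oracle)
    if (nrow(cc$table)) {
      for (lab in cc$table$label) {
        idx <- which(oracle == lab, arr.ind = TRUE)
        expect_equal(cc$table$area[cc$table$label == lab], nrow(idx))
        expect_equal(cc$table$centroid_x[cc$table$label == lab],
                     mean(idx[, 2] - 1))
        expect_equal(cc$table$centroid_y[cc$table$label == lab],
                     mean(idx[, 1] - 1))
      }
    }
  }
})

make_cc <- function(blobs, shape = c(120, 120)) {
  # blobs: list of c(x0, y0, w, h) axis-aligned rectangles (0-based)
  m <- matrix(0, shape[1], shape[2])
  for (b in blobs) m[b[2] + 1:b[4], b[1] + 1:b[3]] <- 1
  connected_components(m)
}

test_that("retention keeps the main component and nearby large secondaries", {
  p <- retention_params(100)  # tau_dist 50, tau_area 100
  # main: 40x25 = 1000 px centered (50, 50); candidate 15x10 = 150 at (80, 50)
  cc <- make_cc(list(c(30, 38, 41, 25), c(73, 45, 15, 10)))
  out <- retain_components(cc, p)
  expect_true(all(out$table$retained))

  # small candidate (area 5 <= 100) rejected
  cc2 <- make_cc(list(c(30, 38, 41, 25), c(60, 60, 5, 1)))
  out2 <- retain_components(cc2, p)
  expect_equal(sum(out2$table$retained), 1)
  expect_equal(sum(out2$mask), sum(out2$table$area[out2$table$retained]))

  # distant candidate (150 px away >= 50) rejected
  cc3 <- make_cc(list(c(30, 38, 41, 25), c(13, 100, 15, 10)), c(140, 140))
  out3 <- retain_components(cc3, p)
  expect_equal(out3$table$retained, c(TRUE, FALSE))

  # empty component list: empty mask, no error
  out4 <- retain_components(connected_components(matrix(0, 5, 5)), p)
  expect_equal(sum(out4$mask), 0)
})

test_that("retention equals the exhaustive predicate on random component sets", {
  set.seed(15)
  for (rep in 1:200) {
    n <- sample(1:8, 1)
    tab <- data.frame(label = 1:n,
                      area = sample(1:400, n, replace = TRUE),
                      centroid_x = runif(n, 0, 120),
                      centroid_y = runif(n, 0, 120))
    h <- runif(1, 20, 120)
    p <- retention_params(h)
    cc <- list(labels = matrix(0L, 1, 1), table = tab)
    out <- retain_components(cc, p)
    expect_equal(out$table$retained, bf_retention(tab, p$tau_dist, p$tau_area))
  }
})

test_that("the full chain preserves the containment hierarchy", {
  set.seed(16)
  g <- matrix(0, 60, 80)
  g[20:30, 10:60] <- 200
  g[45, 70] <- 180
  g <- g + matrix(sample(0:3, 60 * 80, TRUE), 60, 80)
  params <- retention_params(40)
  out <- postprocess_mask(g, params, tau = 1)
  dil <- browquant:::ebi_dilate(out$binary, params$kernel_dilate)
  expect_true(all(out$mask <= out$refined))
  expect_true(all(out$refined <= dil))
})

test_that("tau sensitivity reports the foreground change between thresholds", {
  g <- matrix(0, 50, 50)
  g[10:40, 10:40] <- 150
  g[5, c(5, 45)] <- 5  # weak pixels that disappear at the higher threshold
  params <- retention_params(30)
  s <- tau_sensitivity(g, params, 1, 10)
  expect_gte(s$area_low, s$area_high)
  expect_equal(s$percent_change,
               100 * (s$area_low - s$area_high) / s$area_low)
})
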