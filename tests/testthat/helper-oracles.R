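# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own code paths.

# O(n^3) convex hull: a directed edge (i, j) is on the hull iff every other
# point lies on its left (or on the line); hull vertices are the endpoints.
bf_hull_vertices <- function(pts) {
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- TRUE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      cross <- (pts[j, 1] - pts[i, 1]) * (pts[k, 2] - pts[i, 2]) -
        (pts[j, 2] - pts[i, 2]) * (pts[k, 1] - pts[i, 1])
      if (cross < -1e-9) { ok <- FALSE; break }
    }
    if (ok) { on_hull[i] <- TRUE; on_hull[j] <- TRUE }
  }
  pts[on_hull, , drop = FALSE]
}

# flood-fill 8-connected labeling, scan order row-major (top-to-bottom rows)
bf_flood_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (mask[y, x] > 0 && lab[y, x] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(y, x)); lab[y, x] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dy in -1:1) for (dx in -1:1) {
          yy <- p[1] + dy; xx <- p[2] + dx
          if (yy >= 1 && yy <= h && xx >= 1 && xx <= w &&
              mask[yy, xx] > 0 && lab[yy, xx] == 0L) {
            lab[yy, xx] <- nxt
            queue[[length(queue) + 1]] <- c(yy, xx)
          }
        }
      }
    }
  }
  lab
}

# ICC(2,1) through R's own two-way ANOVA fit (independent of the package's
# direct sums-of-squares implementation)
bf_icc_aov <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), times = k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# exhaustive evaluation of the component-retention predicate
bf_retention <- function(tab, tau_dist, tau_area) {
  main <- tab$label[order(-tab$area, tab$label)][1]
  keep <- logical(nrow(tab))
  mx <- tab$centroid_x[tab$label == main]
  my <- tab$centroid_y[tab$label == main]
  for (i in seq_len(nrow(tab))) {
    if (tab$label[i] == main) { keep[i] <- TRUE; next }
    d <- sqrt((tab$centroid_x[i] - mx)^2 + (tab$centroid_y[i] - my)^2)
    keep[i] <- d < tau_dist && tab$area[i] > tau_area
  }
  keep
}

# small RGB raster with uniform noise, for photometric tests
random_rgb <- function(h, w, lo = 0, hi = 255) {
  array(sample(lo:hi, h * w * 3, replace = TRUE), c(h, w, 3))
}

# one rendered periocular ROI (feature-rich grayscale fixture) for
# registration tests; cached per session
roi_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ses <- render_session(scene_spec(retention = 1, captures = 1, seed = 99))
      cap <- ses$timepoints$T1$captures[[1]]
      roi <- extract_roi(cap$landmarks, 1, 12, cap$image)
      cache <<- list(raster = roi$raster, box = roi$box,
                     landmarks = cap$landmarks, session = ses)
    }
    cache
  }
})
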