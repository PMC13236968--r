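#' Apply a homography to points
#'
#' @param H 3x3 projective matrix.
#' @param pts two-column (x, y) matrix.
#' @return transformed two-column matrix.
#' @export
apply_homography <- function(H, pts) {
  pts <- rbind(pts)
  ph <- H %*% rbind(t(pts), 1)
  t(ph[1:2, , drop = FALSE] / rep(ph[3, ], each = 2))
}

normalize_h <- function(H) {
  if (abs(H[3, 3]) < .Machine$double.eps) stop("degenerate homography (h33 = 0)")
  H / H[3, 3]
}

# Hartley point normalization: centroid to origin, mean distance sqrt(2)
norm_transform <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  md <- mean(d)
  if (md < 1e-12) stop("degenerate configuration: coincident points")
  sc <- sqrt(2) / md
  rbind(c(sc, 0, -sc * ctr[1]),
        c(0, sc, -sc * ctr[2]),
        c(0, 0, 1))
}

dlt_homography <- function(src, dst) {
  Ts <- norm_transform(src); Td <- norm_transform(dst)
  s <- apply_homography(Ts, src); d <- apply_homography(Td, dst)
  n <- nrow(s)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  if (abs(Hn[3, 3]) < 1e-12 || !all(is.finite(Hn)))
    stop("degenerate point configuration for homography estimation")
  normalize_h(solve(Td) %*% Hn %*% Ts)
}

#' Estimate a homography from point correspondences
#'
#' Normalized direct linear transform (DLT). With `robust = TRUE`, a
#' consensus-sampling (RANSAC) stage precedes the final least-squares fit:
#' minimal 4-point models are sampled, inliers are counted at
#' `inlier_thresh` pixels of reprojection error, and the final DLT is fit on
#' the best inlier set (ties broken by the lexicographically lowest inlier
#' index set, for determinism). Sampling uses R's RNG; seed it for
#' reproducible runs.
#'
#' @param src,dst two-column (x, y) matrices of matched points (N >= 4).
#' @param robust enable consensus-based outlier rejection.
#' @param inlier_thresh inlier reprojection threshold (px).
#' @param max_iter number of consensus samples.
#' @return 3x3 matrix (bottom-right entry 1) with attribute `"inliers"`
#'   (integer indices of the correspondences used in the final fit).
#' @export
estimate_homography <- function(src, dst, robust = FALSE,
                                inlier_thresh = 3, max_iter = 500) {
  src <- rbind(src); dst <- rbind(dst)
  n <- nrow(src)
  if (n < 4 || nrow(dst) != n)
    stop("insufficient correspondences: need N >= 4 matched points")
  if (!robust || n == 4) {
    H <- dlt_homography(src, dst)
    attr(H, "inliers") <- seq_len(n)
    return(H)
  }
  best_inl <- integer(0)
  for (iter in seq_len(max_iter)) {
    idx <- sample.int(n, 4)
    H <- tryCatch(dlt_homography(src[idx, ], dst[idx, ]), error = function(e) NULL)
    if (is.null(H)) next
    err <- sqrt(rowSums((apply_homography(H, src) - dst)^2))
    inl <- which(err < inlier_thresh)
    if (length(inl) > length(best_inl) ||
        (length(inl) == length(best_inl) && length(inl) > 0 &&
         paste(inl, collapse = ",") < paste(best_inl, collapse = ","))) {
      best_inl <- inl
    }
  }
  if (length(best_inl) < 4)
    stop("consensus sampling found no 4-point inlier set")
  H <- dlt_homography(src[best_inl, , drop = FALSE], dst[best_inl, , drop = FALSE])
  attr(H, "inliers") <- best_inl
  H
}

#' Root-mean-square reprojection error
#'
#' @inheritParams estimate_homography
#' @param H homography mapping `src` towards `dst`.
#' @return RMSE in pixels.
#' @export
rmse_reprojection <- function(src, dst, H) {
  src <- rbind(src); dst <- rbind(dst)
  proj <- apply_homography(H, src)
  sqrt(mean(rowSums((dst - proj)^2)))
}

#' Perspective warp of a raster
#'
#' Inverse-mapping warp: each target pixel (x, y) is sampled from the source
#' at `H^-1 (x, y)`. Bilinear interpolation for intensity rasters,
#' nearest-neighbor for masks and trimaps (never introducing new label
#' values). Samples falling outside the source are 0 (zero padding).
#'
#' @param raster source raster (`H x W` or `H x W x 3`, any scale).
#' @param H homography mapping source coordinates to target coordinates.
#' @param target_shape `c(height, width)` of the output (default: source).
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return warped raster of shape `target_shape`.
#' @export
warp_image <- function(raster, H, target_shape = dim(raster)[1:2],
                       interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot_raster(raster)
  Hi <- tryCatch(solve(H), error = function(e) stop("singular homography"))
  th <- target_shape[1]; tw <- target_shape[2]
  gx <- rep(0:(tw - 1), each = th)
  gy <- rep(0:(th - 1), times = tw)
  ph <- Hi %*% rbind(gx, gy, 1)
  u <- ph[1, ] / ph[3, ]
  v <- ph[2, ] / ph[3, ]
  sh <- dim(raster)[1]; sw <- dim(raster)[2]
  nch <- if (length(dim(raster)) == 3L) dim(raster)[3] else 1L
  out <- array(0, c(th, tw, nch))
  if (interpolation == "nearest") {
    ui <- round(u); vi <- round(v)
    ok <- ui >= 0 & ui <= (sw - 1) & vi >= 0 & vi <= (sh - 1)
    idx <- vi[ok] + 1 + ui[ok] * sh
    for (ch in seq_len(nch)) {
      plane <- if (nch == 1L && length(dim(raster)) == 2L) raster else raster[, , ch]
      o <- matrix(0, th, tw)
      o[which(ok)] <- plane[idx]
      out[, , ch] <- o
    }
  } else {
    ok <- u >= 0 & u <= (sw - 1) & v >= 0 & v <= (sh - 1)
    x0k <- floor(u[ok]); y0k <- floor(v[ok])
    fxk <- u[ok] - x0k; fyk <- v[ok] - y0k
    x1k <- pmin(x0k + 1, sw - 1); y1k <- pmin(y0k + 1, sh - 1)
    for (ch in seq_len(nch)) {
      plane <- if (nch == 1L && length(dim(raster)) == 2L) raster else raster[, , ch]
      p00 <- plane[y0k + 1 + x0k * sh]; p10 <- plane[y0k + 1 + x1k * sh]
      p01 <- plane[y1k + 1 + x0k * sh]; p11 <- plane[y1k + 1 + x1k * sh]
      val <- p00 * (1 - fxk) * (1 - fyk) + p10 * fxk * (1 - fyk) +
        p01 * (1 - fxk) * fyk + p11 * fxk * fyk
      o <- matrix(0, th, tw)
      o[which(ok)] <- val
      out[, , ch] <- o
    }
  }
  if (nch == 1L) out[, , 1] else out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  outer(k, k)
}

conv2 <- function(m, kern) {
  EBImage::imageData(EBImage::filter2(EBImage::Image(m), kern,
                                      boundary = "replicate"))
}

#' Harris corner detection
#'
#' Classical Harris response (structure tensor smoothed with a Gaussian,
#' `R = det - k * trace^2`) followed by 3x3 non-maximum suppression. Returns
#' the strongest corners at least `border` px from the edge.
#'
#' @param gray grayscale raster (0-255).
#' @param k Harris sensitivity constant.
#' @param sigma Gaussian integration scale (px).
#' @param n_max maximum number of corners returned.
#' @param border minimum distance from the image border (px).
#' @return two-column (x, y) matrix of corner locations (0-based).
#' @export
harris_corners <- function(gray, k = 0.04, sigma = 1.5, n_max = 400,
                           border = 6) {
  sob <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1)) / 8
  gx <- conv2(gray, t(sob))
  gy <- conv2(gray, sob)
  g <- gaussian_kernel(sigma)
  sxx <- conv2(gx * gx, g); syy <- conv2(gy * gy, g); sxy <- conv2(gx * gy, g)
  R <- (sxx * syy - sxy^2) - k * (sxx + syy)^2
  h <- nrow(R); w <- ncol(R)
  pad <- matrix(-Inf, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- R
  ismax <- R >= pmax(
    pad[1:h, 1:w], pad[1:h, 2:(w + 1)], pad[1:h, 3:(w + 2)],
    pad[2:(h + 1), 1:w], pad[2:(h + 1), 3:(w + 2)],
    pad[3:(h + 2), 1:w], pad[3:(h + 2), 2:(w + 1)], pad[3:(h + 2), 3:(w + 2)]
  )
  thr <- 1e-6 * max(R)
  cand <- which(ismax & R > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  x <- cand[, 2] - 1; y <- cand[, 1] - 1
  keep <- x >= border & x <= (w - 1 - border) & y >= border & y <= (h - 1 - border)
  x <- x[keep]; y <- y[keep]
  resp <- R[cbind(y + 1, x + 1)]
  ord <- order(-resp, y, x)  # deterministic on response ties
  ord <- ord[seq_len(min(n_max, length(ord)))]
  x <- x[ord]; y <- y[ord]; r0 <- resp[ord]
  # subpixel localization: 1-D parabolic fit of the response around the peak
  subpix <- function(rm, rp) {
    den <- rm - 2 * r0 + rp
    d <- ifelse(abs(den) > 1e-12, 0.5 * (rm - rp) / den, 0)
    pmin(pmax(d, -0.5), 0.5)
  }
  dx <- subpix(R[cbind(y + 1, x)], R[cbind(y + 1, x + 2)])
  dy <- subpix(R[cbind(y, x + 1)], R[cbind(y + 2, x + 1)])
  cbind(x = x + dx, y = y + dy)
}

patch_descriptors <- function(gray, pts, radius = 5) {
  n <- nrow(pts)
  d <- matrix(0, (2 * radius + 1)^2, n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    x <- pts[i, 1]; y <- pts[i, 2]
    p <- gray[(y - radius + 1):(y + radius + 1), (x - radius + 1):(x + radius + 1)]
    v <- as.numeric(p) - mean(p)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) { d[, i] <- v / nv; ok[i] <- TRUE }
  }
  list(desc = d, ok = ok)
}

#' Detect and match local features between two rasters
#'
#' Bundled classical feature backend: Harris corners with normalized
#' patch descriptors, matched by normalized cross-correlation with a mutual
#' best-match constraint. Serves as the default plugin for the fine
#' registration stage; a learned detector can be substituted through the
#' same interface (`function(rasterA, rasterB) -> list(src, dst)`).
#'
#' @param a,b grayscale or RGB rasters (0-255).
#' @param min_ncc minimum correlation accepted for a match.
#' @param patch_radius descriptor patch radius (px).
#' @param n_max maximum corners per image.
#' @return list with `src` (points in `a`) and `dst` (points in `b`),
#'   two-column (x, y) matrices of equal row count.
#' @export
detect_and_match <- function(a, b, min_ncc = 0.7, patch_radius = 5,
                             n_max = 400) {
  ga <- luminance_v(a); gb <- luminance_v(b)
  border <- patch_radius + 1
  pa <- harris_corners(ga, n_max = n_max, border = border)
  pb <- harris_corners(gb, n_max = n_max, border = border)
  empty <- list(src = matrix(numeric(0), 0, 2), dst = matrix(numeric(0), 0, 2))
  if (nrow(pa) == 0 || nrow(pb) == 0) return(empty)
  da <- patch_descriptors(ga, round(pa), patch_radius)
  db <- patch_descriptors(gb, round(pb), patch_radius)
  ia <- which(da$ok); ib <- which(db$ok)
  if (length(ia) == 0 || length(ib) == 0) return(empty)
  ncc <- crossprod(da$desc[, ia, drop = FALSE], db$desc[, ib, drop = FALSE])
  best_ab <- max.col(ncc, ties.method = "first")
  best_ba <- max.col(t(ncc), ties.method = "first")
  i <- seq_along(ia)
  mutual <- best_ba[best_ab] == i
  score <- ncc[cbind(i, best_ab)]
  # ambiguity test: drop matches whose runner-up correlates almost as well
  # (guards against aliasing between quasi-periodic hair strands)
  ncc2 <- ncc; ncc2[cbind(i, best_ab)] <- -Inf
  second <- apply(ncc2, 1, max)
  keep <- mutual & score >= min_ncc & (score - second) >= 0.02
  src <- round(pa[ia[keep], , drop = FALSE])
  dst <- round(pb[ib[best_ab[keep]], , drop = FALSE])
  list(src = src,
       dst = refine_matches(ga, gb, src, dst, radius = patch_radius + 3))
}

# Subpixel refinement of matched positions: the destination point is moved
# to the parabolic-interpolated peak of the local normalized correlation
# surface (evaluated on a 3x3 integer-offset grid around the match).
refine_matches <- function(ga, gb, src, dst, radius = 5) {
  if (nrow(src) == 0) return(dst)
  hB <- nrow(gb); wB <- ncol(gb)
  out <- dst
  offs <- -1:1
  hA <- nrow(ga); wA <- ncol(ga)
  for (i in seq_len(nrow(src))) {
    xa <- src[i, 1]; ya <- src[i, 2]
    if (xa - radius < 0 || xa + radius > wA - 1 ||
        ya - radius < 0 || ya + radius > hA - 1) next
    pa <- ga[(ya - radius + 1):(ya + radius + 1),
             (xa - radius + 1):(xa + radius + 1)]
    va <- as.numeric(pa) - mean(pa)
    na <- sqrt(sum(va^2))
    if (na < 1e-8) next
    ncc_at <- function(xb, yb) {
      if (xb - radius < 0 || xb + radius > wB - 1 ||
          yb - radius < 0 || yb + radius > hB - 1) return(NA_real_)
      pb <- gb[(yb - radius + 1):(yb + radius + 1),
               (xb - radius + 1):(xb + radius + 1)]
      vb <- as.numeric(pb) - mean(pb)
      nb <- sqrt(sum(vb^2))
      if (nb > 1e-8) sum(va * vb) / (na * nb) else NA_real_
    }
    xb <- dst[i, 1]; yb <- dst[i, 2]
    # recentre on the local integer NCC peak (up to 2 steps), then fit
    for (step in 1:2) {
      cc <- matrix(NA_real_, 3, 3)
      for (du in offs) for (dv in offs)
        cc[dv + 2, du + 2] <- ncc_at(xb + du, yb + dv)
      if (any(is.na(cc))) { cc <- NULL; break }
      pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (all(pk == c(2, 2))) break
      xb <- xb + (pk[2] - 2); yb <- yb + (pk[1] - 2)
      cc <- NULL
    }
    if (is.null(cc)) next
    den_u <- cc[2, 1] - 2 * cc[2, 2] + cc[2, 3]
    den_v <- cc[1, 2] - 2 * cc[2, 2] + cc[3, 2]
    du <- if (is.finite(den_u) && abs(den_u) > 1e-12)
      min(max(0.5 * (cc[2, 1] - cc[2, 3]) / den_u, -0.5), 0.5) else 0
    dv <- if (is.finite(den_v) && abs(den_v) > 1e-12)
      min(max(0.5 * (cc[1, 2] - cc[3, 2]) / den_v, -0.5), 0.5) else 0
    out[i, ] <- c(xb + du, yb + dv)
  }
  out
}

#' Two-stage coarse-to-fine registration to the baseline frame
#'
#' Stage 1 estimates a coarse homography from corresponding periocular
#' landmarks (ROI-local coordinates) and warps the follow-up ROI into the
#' baseline grid. Stage 2 detects and matches local features between the
#' coarsely aligned ROI and the baseline ROI and estimates a fine residual
#' homography (robust by default). The total mapping is the matrix product
#' `H_total = H2 %*% H1`. If the feature stage yields fewer than 4 matches,
#' the fine stage falls back to the identity and the chain is flagged.
#'
#' @param roi_t follow-up ROI raster.
#' @param roi_t1 baseline ROI raster (defines the target grid).
#' @param lm_t,lm_t1 matched landmark matrices in each ROI's local frame
#'   (same index order).
#' @param feature_backend plugin `function(a, b) -> list(src, dst)`.
#' @param robust use consensus-based outlier rejection in the fine stage.
#' @param inlier_thresh fine-stage inlier threshold (px).
#' @param max_fine_displacement plausibility bound (px) on the fine
#'   homography's displacement at the ROI corners; the fine stage only
#'   corrects residual local misalignment, so a fit that moves any corner
#'   further than this (typically an ill-conditioned consensus on few,
#'   spatially clustered matches) is rejected and replaced by the identity,
#'   with the fallback flag set.
#' @return list of class `homography_chain`: `H1`, `H2`, `H_total`,
#'   `rmse_coarse` (landmarks under H1), `rmse_fine` (feature inliers under
#'   H2), `rmse_fine_all` (all feature matches), `n_matches`,
#'   `fine_fallback`, and `registered` (the fully warped ROI).
#' @export
register_two_stage <- function(roi_t, roi_t1, lm_t, lm_t1,
                               feature_backend = detect_and_match,
                               robust = TRUE, inlier_thresh = 3,
                               max_fine_displacement = 15) {
  stopifnot_raster(roi_t); stopifnot_raster(roi_t1)
  if (nrow(rbind(lm_t)) != nrow(rbind(lm_t1)))
    stop("landmark sets must share indices")
  shape <- dim(roi_t1)[1:2]
  H1 <- estimate_homography(lm_t, lm_t1, robust = FALSE)
  tr1 <- warp_image(roi_t, H1, target_shape = shape, interpolation = "bilinear")
  rmse_coarse <- rmse_reprojection(lm_t, lm_t1, H1)

  m <- feature_backend(tr1, roi_t1)
  fine_fallback <- FALSE
  rmse_fine <- rmse_fine_all <- NA_real_
  if (nrow(m$src) >= 4) {
    H2 <- tryCatch(
      estimate_homography(m$src, m$dst, robust = robust,
                          inlier_thresh = inlier_thresh),
      error = function(e) NULL)
    if (is.null(H2)) {
      H2 <- diag(3); fine_fallback <- TRUE
    } else {
      corners <- rbind(c(0, 0), c(shape[2] - 1, 0), c(0, shape[1] - 1),
                       c(shape[2] - 1, shape[1] - 1))
      disp <- apply_homography(H2, corners) - corners
      if (max(abs(disp)) > max_fine_displacement) {
        H2 <- diag(3); fine_fallback <- TRUE
      } else {
        inl <- attr(H2, "inliers")
        rmse_fine <- rmse_reprojection(m$src[inl, , drop = FALSE],
                                       m$dst[inl, , drop = FALSE], H2)
        rmse_fine_all <- rmse_reprojection(m$src, m$dst, H2)
      }
    }
  } else {
    H2 <- diag(3)
    fine_fallback <- TRUE
  }
  tr2 <- warp_image(tr1, H2, target_shape = shape, interpolation = "bilinear")
  H_total <- normalize_h(H2 %*% H1)
  # pixels of the target grid actually observed in the source ROI (the
  # zero-padded fringe of the warp is not measurement support)
  ones <- matrix(1, dim(roi_t)[1], dim(roi_t)[2])
  valid <- warp_image(ones, H_total, target_shape = shape,
                      interpolation = "nearest") > 0
  structure(list(
    H1 = H1, H2 = normalize_h(H2), H_total = H_total,
    rmse_coarse = rmse_coarse, rmse_fine = rmse_fine,
    rmse_fine_all = rmse_fine_all, n_matches = nrow(m$src),
    fine_fallback = fine_fallback, registered = tr2, valid = valid
  ), class = "homography_chain")
}

#' @export
print.homography_chain <- function(x, ...) {
  cat(sprintf("<homography_chain: rmse_coarse=%.3f px, rmse_fine=%.3f px, matches=%d%s>\n",
              x$rmse_coarse, x$rmse_fine, x$n_matches,
              if (x$fine_fallback) ", fine stage fell back to identity" else ""))
  invisible(x)
}

#' Serialize a homography chain to JSON
#'
#' Row-major 3x3 arrays with stage labels and RMSE values.
#'
#' @param chain `homography_chain`.
#' @param path output JSON path.
#' @export
write_homography_chain <- function(chain, path) {
  mat_rows <- function(M) lapply(seq_len(3), function(i) unname(M[i, ]))
  jsonlite::write_json(list(
    H1 = mat_rows(chain$H1), H2 = mat_rows(chain$H2),
    H_total = mat_rows(chain$H_total),
    rmse_coarse_px = chain$rmse_coarse, rmse_fine_px = chain$rmse_fine,
    rmse_fine_all_px = chain$rmse_fine_all,
    n_matches = chain$n_matches, fine_fallback = chain$fine_fallback
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
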