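#' Trimap-guided soft hair segmentation
#'
#' Dispatches the ROI and its trimap to a matting backend and enforces the
#' trimap contract on the result: pixels labeled definite background map to
#' probability 0, definite foreground to 1, and only the unknown region
#' carries backend-estimated values. The output is a per-pixel probability
#' map `p in [0, 1]` — the likelihood of belonging to the hair structure —
#' preserving fine strand detail that hard binary segmentation would lose.
#'
#' @param roi RGB ROI raster (0-255), registered to the baseline frame.
#' @param tm a [trimap()] of the same shape.
#' @param backend backend id (`"baseline"`) or a plugin
#'   `function(roi, tm) -> matrix of p in [0, 1]`.
#' @return matrix of probabilities with attribute `"backend_id"`.
#' @export
segment_hair <- function(roi, tm, backend = "baseline") {
  stopifnot_raster(roi)
  if (!inherits(tm, "trimap")) stop("tm must be a trimap")
  if (!all(dim(tm$mask) == dim(roi)[1:2]))
    stop("shape mismatch between ROI and trimap")
  backend_id <- if (is.function(backend)) "custom" else backend
  fn <- if (is.function(backend)) backend
        else switch(backend, baseline = matting_backend_baseline,
                    stop("unknown matting backend: ", backend))
  p <- tryCatch(fn(roi, tm),
                error = function(e) stop("matting backend '", backend_id,
                                         "' failed: ", conditionMessage(e)))
  if (any(p < 0 | p > 1)) stop("backend '", backend_id,
                               "' produced probabilities outside [0, 1]")
  p[tm$mask == TRIMAP_BG] <- 0
  p[tm$mask == TRIMAP_FG] <- 1
  attr(p, "backend_id") <- backend_id
  p
}

#' Baseline intensity-split matting backend
#'
#' Classical trimap-constrained backend requiring no learned weights: the
#' luminance values of the unknown region are split into two clusters
#' (dark hair vs bright skin) by 2-class k-means with deterministic
#' min/max initialization. Pixels assigned to the dark (hair) cluster get
#' `p = clip((mu_skin - L) / (mu_skin - mu_dark), 0, 1)`, the linear ramp
#' between the two cluster centers, so anti-aliased strand edges receive
#' fractional opacity; pixels assigned to the skin cluster get `p = 0`,
#' keeping the map near-zero on skin the way a trained matting network
#' behaves (an ungated ramp would leak small positive probabilities onto
#' every skin pixel darker than the cluster mean, which the downstream
#' high-sensitivity threshold would count as hair). Deterministic for fixed
#' input.
#'
#' @param roi RGB (or grayscale) ROI raster (0-255).
#' @param tm a [trimap()].
#' @return probability matrix (0 outside the unknown region; a warning and
#'   an all-zero map if the unknown region has fewer than 2 distinct
#'   intensities).
#' @export
matting_backend_baseline <- function(roi, tm) {
  L <- luminance_v(roi)
  p <- matrix(0, nrow(L), ncol(L))
  unk <- tm$mask == TRIMAP_UNKNOWN
  vals <- L[unk]
  if (length(unique(vals)) < 2) {
    warning("unknown region has < 2 distinct intensities; returning empty map")
    return(p)
  }
  km <- stats::kmeans(vals, centers = matrix(range(vals), ncol = 1),
                      iter.max = 50)
  mu_dark <- min(km$centers); mu_skin <- max(km$centers)
  dark <- vals < (mu_dark + mu_skin) / 2
  pv <- numeric(length(vals))
  pv[dark] <- pmin(pmax((mu_skin - vals[dark]) / (mu_skin - mu_dark), 0), 1)
  p[unk] <- pv
  p
}

#' Probability map <-> 8-bit grayscale
#'
#' Probability maps are stored as single-channel 8-bit PNG (`p * 255`,
#' rounded), the representation consumed by the post-processing stage.
#'
#' @param p probability matrix in [0, 1].
#' @return matrix of integers 0-255.
#' @export
prob_to_gray8 <- function(p) round(p * 255)

#' @param path PNG path.
#' @rdname prob_to_gray8
#' @export
write_probability_map <- function(p, path) {
  png::writePNG(prob_to_gray8(p) / 255, path)
  invisible(path)
}
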