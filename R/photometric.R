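#' HSV decomposition of an RGB raster
#'
#' Standard hexcone model: V = max(R, G, B) on the 0-255 scale,
#' S = (V - min) / V (0 where V = 0), H in degrees [0, 360).
#'
#' @param raster RGB raster (`H x W x 3`, 0-255).
#' @return list of `h`, `s`, `v` matrices.
#' @export
rgb_to_hsv_channels <- function(raster) {
  stopifnot_raster(raster)
  r <- raster[, , 1]; g <- raster[, , 2]; b <- raster[, , 3]
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  c_ <- v - mn
  s <- ifelse(v > 0, c_ / v, 0)
  h <- matrix(0, nrow(v), ncol(v))
  nz <- c_ > 0
  hr <- nz & v == r
  hg <- nz & v == g & !hr
  hb <- nz & !hr & !hg
  h[hr] <- ((g[hr] - b[hr]) / c_[hr]) %% 6
  h[hg] <- (b[hg] - r[hg]) / c_[hg] + 2
  h[hb] <- (r[hb] - g[hb]) / c_[hb] + 4
  list(h = h * 60, s = s, v = v)
}

#' Recompose an RGB raster from HSV channels
#'
#' Exact numeric inverse of [rgb_to_hsv_channels()] (before any 8-bit
#' quantization).
#'
#' @param h,s,v hue (degrees), saturation [0,1], value [0,255] matrices.
#' @return RGB raster, floating point 0-255.
#' @export
hsv_to_rgb_channels <- function(h, s, v) {
  hp <- (h / 60) %% 6
  c_ <- v * s
  x <- c_ * (1 - abs(hp %% 2 - 1))
  m <- v - c_
  r <- g <- b <- matrix(0, nrow(v), ncol(v))
  sect <- floor(hp)
  pick <- function(i) sect == i
  r[pick(0)] <- c_[pick(0)]; g[pick(0)] <- x[pick(0)]
  r[pick(1)] <- x[pick(1)];  g[pick(1)] <- c_[pick(1)]
  g[pick(2)] <- c_[pick(2)]; b[pick(2)] <- x[pick(2)]
  g[pick(3)] <- x[pick(3)];  b[pick(3)] <- c_[pick(3)]
  r[pick(4)] <- x[pick(4)];  b[pick(4)] <- c_[pick(4)]
  r[pick(5)] <- c_[pick(5)]; b[pick(5)] <- x[pick(5)]
  out <- array(0, c(nrow(v), ncol(v), 3))
  out[, , 1] <- r + m; out[, , 2] <- g + m; out[, , 3] <- b + m
  out
}

#' Baseline photometric reference
#'
#' The reference luminance `V_ref` is the mean of the HSV value channel of
#' the baseline (T1) ROI; follow-up ROIs are shifted to match it.
#'
#' @param roi baseline RGB ROI raster (0-255).
#' @return object of class `photometric_ref` with field `v_ref`.
#' @export
compute_reference <- function(roi) {
  stopifnot_raster(roi)
  v <- luminance_v(roi)
  structure(list(v_ref = mean(v)), class = "photometric_ref")
}

#' Baseline-referenced luminance normalization
#'
#' Applies a global offset `V_ref - mean(V)` to the HSV value channel of the
#' ROI, clips to the 8-bit range, and converts back to RGB. Hue and
#' saturation are untouched, so only brightness is aligned to the baseline
#' session; with `quantize = FALSE` the H and S channels of the output are
#' bit-identical to the input's. With `quantize = TRUE` (default) the RGB
#' output is rounded half-to-even to integers at the very end, which can
#' perturb recomputed H/S by at most the quantization step.
#'
#' @param roi RGB ROI raster (0-255).
#' @param ref `photometric_ref` from [compute_reference()].
#' @param quantize round the output to 8-bit integers.
#' @return normalized RGB raster; the applied offset is attached as
#'   attribute `"offset"`.
#' @export
normalize_luminance <- function(roi, ref, quantize = TRUE) {
  stopifnot_raster(roi)
  if (!inherits(ref, "photometric_ref")) stop("ref must be a photometric_ref")
  ch <- rgb_to_hsv_channels(roi)
  offset <- ref$v_ref - mean(ch$v)
  v2 <- pmin(pmax(ch$v + offset, 0), 255)
  out <- hsv_to_rgb_channels(ch$h, ch$s, v2)
  if (quantize) out <- round(out)  # round() is half-to-even
  attr(out, "offset") <- offset
  out
}
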