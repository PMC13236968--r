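TRIMAP_BG <- 0
TRIMAP_UNKNOWN <- 128
TRIMAP_FG <- 255

#' Trimap container
#'
#' A trimap partitions the ROI into definite background (0), an unknown
#' transition band (128) where the matting backend refines the hair/skin
#' boundary, and optional definite foreground (255).
#'
#' @param mask matrix with values in `{0, 128, 255}`, ROI-local frame.
#' @param delta vertical expansion offset used to build it (px).
#' @param provenance `"generated_at_T1"` or `"propagated"`.
#' @return object of class `trimap`.
#' @export
trimap <- function(mask, delta = NA_real_,
                   provenance = c("generated_at_T1", "propagated")) {
  provenance <- match.arg(provenance)
  if (!all(mask %in% c(TRIMAP_BG, TRIMAP_UNKNOWN, TRIMAP_FG)))
    stop("trimap labels must be in {0, 128, 255}")
  structure(list(mask = mask, delta = delta, provenance = provenance),
            class = "trimap")
}

#' @export
print.trimap <- function(x, ...) {
  cat(sprintf("<trimap %dx%d, delta=%.2f px, %s; unknown=%d px, fg=%d px>\n",
              nrow(x$mask), ncol(x$mask), x$delta, x$provenance,
              sum(x$mask == TRIMAP_UNKNOWN), sum(x$mask == TRIMAP_FG)))
  invisible(x)
}

#' Adaptive vertical expansion of eyebrow landmarks
#'
#' Shifts the upper eyebrow landmarks upward and the lower ones downward by
#' the adaptive offset `delta` (image y grows downward, so upper points get
#' `y - delta`). Upper/lower classification is relative to the vertical
#' midline of the polygon's bounding box. The offset is proportional to the
#' eyebrow height (30% by default) so the safety band scales with the
#' subject's anatomy and captures stray hairs.
#'
#' @param polygon ordered two-column (x, y) eyebrow landmark matrix.
#' @param delta vertical offset (px, >= 0).
#' @return expanded two-column point matrix.
#' @export
expand_landmarks <- function(polygon, delta) {
  polygon <- rbind(polygon)
  if (delta < 0) stop("delta must be >= 0")
  if (nrow(polygon) < 3) stop("eyebrow polygon needs at least 3 points")
  mid <- mean(range(polygon[, 2]))
  upper <- polygon[, 2] < mid
  out <- polygon
  out[upper, 2] <- out[upper, 2] - delta
  out[!upper, 2] <- out[!upper, 2] + delta
  out
}

# Rasterize a filled convex polygon (vertex matrix, 0-based coords) onto an
# h x w grid by half-plane tests; boundary pixels included.
fill_convex_polygon <- function(vertices, shape) {
  h <- shape[1]; w <- shape[2]
  hull_idx <- grDevices::chull(vertices)
  hv <- vertices[hull_idx, , drop = FALSE]  # clockwise order from chull
  n <- nrow(hv)
  if (n < 3) stop("degenerate (collinear) point set: convex hull is not a polygon")
  nxt <- c(2:n, 1)
  orient <- sign(sum(hv[, 1] * hv[nxt, 2] - hv[nxt, 1] * hv[, 2]))
  if (orient == 0) stop("degenerate (collinear) point set: convex hull is not a polygon")
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  inside <- matrix(TRUE, h, w)
  for (i in seq_len(n)) {
    a <- hv[i, ]; b <- hv[nxt[i], ]
    cross <- (b[1] - a[1]) * (Y - a[2]) - (b[2] - a[2]) * (X - a[1])
    inside <- inside & (orient * cross >= -1e-9)
  }
  inside
}

odd_size <- function(x) max(1L, 2L * as.integer(round((x - 1) / 2)) + 1L)

ebi_dilate <- function(mask, size) {
  if (size < 2) return(mask)
  brush <- EBImage::makeBrush(odd_size(size), shape = "disc")
  EBImage::imageData(EBImage::dilate(EBImage::Image(t(mask)), brush)) |> t()
}

ebi_erode <- function(mask, size) {
  if (size < 2) return(mask)
  brush <- EBImage::makeBrush(odd_size(size), shape = "disc")
  EBImage::imageData(EBImage::erode(EBImage::Image(t(mask)), brush)) |> t()
}

#' Convex hull + morphological dilation into a trimap
#'
#' Computes the convex hull of the (expanded) landmark set, fills it, and
#' dilates it with an elliptical structuring element to add a final safety
#' margin; the dilated hull becomes the unknown region of the trimap. By
#' default no definite-foreground region is marked (the whole hull is
#' "unknown", leaving the decision to the matting backend); optionally an
#' eroded hull core can be labeled definite foreground.
#'
#' @param points two-column (x, y) point matrix (>= 3 non-collinear points),
#'   ROI-local 0-based coordinates.
#' @param dilation_radius safety-margin radius (px); the structuring element
#'   diameter is `2 * round(radius) + 1`.
#' @param shape `c(height, width)` of the ROI raster.
#' @param delta bookkeeping: the vertical offset used upstream.
#' @param fg_core_radius if > 0, erode the filled hull by this radius and
#'   label the core definite foreground.
#' @return a [trimap()].
#' @export
hull_and_dilate <- function(points, dilation_radius, shape,
                            delta = NA_real_, fg_core_radius = 0) {
  filled <- fill_convex_polygon(rbind(points), shape)
  unknown <- if (dilation_radius > 0)
    ebi_dilate(filled * 1, 2 * round(dilation_radius) + 1) > 0
  else filled
  m <- matrix(TRIMAP_BG, shape[1], shape[2])
  m[unknown] <- TRIMAP_UNKNOWN
  if (fg_core_radius > 0) {
    core <- ebi_erode(filled * 1, 2 * round(fg_core_radius) + 1) > 0
    m[core] <- TRIMAP_FG
  }
  if (!any(m == TRIMAP_UNKNOWN)) stop("trimap has an empty unknown region")
  trimap(m, delta = delta, provenance = "generated_at_T1")
}

#' Generate the baseline eyebrow trimap from landmarks
#'
#' Full automated trimap construction: adaptive vertical expansion of the
#' eyebrow polygon by `delta = delta_ratio * h`, convex hull, and
#' morphological dilation by `dilate_ratio * h`, where `h` is the eyebrow
#' height. Generated on the baseline (T1) image and propagated to follow-up
#' timepoints via registration, so the same anatomical support region is
#' evaluated longitudinally.
#'
#' @param brow_polygon eyebrow landmark polygon in ROI-local coordinates.
#' @param h eyebrow reference height (px).
#' @param shape ROI raster shape `c(height, width)`.
#' @param delta_ratio vertical expansion as a fraction of `h` (default 0.30).
#' @param dilate_ratio dilation radius as a fraction of `h` (default 0.10).
#' @param fg_core_ratio optional definite-foreground erosion radius as a
#'   fraction of `h` (default 0: no definite foreground).
#' @return a [trimap()].
#' @export
make_trimap <- function(brow_polygon, h, shape, delta_ratio = 0.30,
                        dilate_ratio = 0.10, fg_core_ratio = 0) {
  delta <- delta_ratio * h
  expanded <- expand_landmarks(brow_polygon, delta)
  hull_and_dilate(expanded, dilation_radius = dilate_ratio * h,
                  shape = shape, delta = delta,
                  fg_core_radius = fg_core_ratio * h)
}

#' Propagate a trimap through a homography
#'
#' Warps the trimap with nearest-neighbor interpolation (labels stay in the
#' 3-value set) into another registered frame; out-of-frame pixels become
#' background.
#'
#' @param tm a [trimap()].
#' @param H homography mapping the trimap's frame to the target frame.
#' @param target_shape `c(height, width)` of the target frame.
#' @return propagated [trimap()].
#' @export
propagate_trimap <- function(tm, H, target_shape = dim(tm$mask)) {
  warped <- warp_image(tm$mask, H, target_shape = target_shape,
                       interpolation = "nearest")
  trimap(warped, delta = tm$delta, provenance = "propagated")
}

#' Trimap PNG round trip
#'
#' Written as single-channel 8-bit PNG with the exact `{0, 128, 255}`
#' palette; the round trip is bit-exact.
#'
#' @param tm a [trimap()].
#' @param path PNG path.
#' @export
write_trimap <- function(tm, path) {
  png::writePNG(tm$mask / 255, path)
  invisible(path)
}

#' @rdname write_trimap
#' @export
read_trimap <- function(path) {
  m <- round(png::readPNG(path) * 255)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  trimap(m)
}
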