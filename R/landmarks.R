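#' Landmark sets and periocular topology
#'
#' A `landmark_set` holds indexed 2-D landmark points for one image together
#' with the coordinate frame they live in (`"resized"`, `"original"` or
#' `"roi_local"`) and the dimensions of that frame. Which indices form the
#' periocular contour of each eye and the eyebrow-support region is a fixed
#' configuration constant (see [periocular_topology()]), never chosen
#' per image.
#'
#' @param points numeric matrix with two columns (x, y), row names giving
#'   the topological indices.
#' @param frame coordinate frame tag.
#' @param width,height dimensions (px) of the image in that frame.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points,
                         frame = c("original", "resized", "roi_local"),
                         width, height) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must have two columns (x, y)")
  if (is.null(rownames(points))) rownames(points) <- seq_len(nrow(points))
  colnames(points) <- c("x", "y")
  if (!all(is.finite(points))) stop("landmark coordinates must be finite")
  structure(
    list(points = points, frame = frame, width = width, height = height),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set: %d points, frame=%s, %dx%d>\n",
              nrow(x$points), x$frame, x$width, x$height))
  invisible(x)
}

#' Default periocular landmark topology
#'
#' Index subsets delimiting, for each eye, the periocular contour used for
#' ROI extraction and coarse registration (`periocular`) and the
#' eyebrow-support polygon used for trimap generation and the proportional
#' reference height (`eyebrow`). The subsets are disjoint between eyes and
#' fixed across all images; any face-mesh topology providing such subsets
#' can be substituted. The defaults match the synthetic scene generator:
#' indices 1-8 / 9-16 are the eye contours, 17-26 / 27-36 the eyebrow
#' polygons of eyes 1 and 2.
#'
#' @return a list with elements `periocular` and `eyebrow`, each a list of
#'   two integer vectors (one per eye).
#' @export
periocular_topology <- function() {
  eye1 <- 1:8; eye2 <- 9:16
  brow1 <- 17:26; brow2 <- 27:36
  list(
    periocular = list(c(eye1, brow1), c(eye2, brow2)),
    eyebrow = list(brow1, brow2)
  )
}

#' Read / write landmark sidecar files
#'
#' Landmark files are JSON with fields `width`, `height`, `frame` and
#' `points` (a map from topological index to `[x, y]`).
#'
#' @param path JSON file path.
#' @return [read_landmarks()] returns a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- do.call(rbind, lapply(j$points, as.numeric))
  rownames(pts) <- names(j$points)
  landmark_set(pts, frame = j$frame, width = j$width, height = j$height)
}

#' @param lms a `landmark_set`.
#' @rdname read_landmarks
#' @export
write_landmarks <- function(lms, path) {
  pts <- lapply(seq_len(nrow(lms$points)), function(i) unname(lms$points[i, ]))
  names(pts) <- rownames(lms$points)
  jsonlite::write_json(
    list(width = lms$width, height = lms$height, frame = lms$frame,
         points = pts),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

lm_subset <- function(lms, idx) {
  keep <- rownames(lms$points) %in% as.character(idx)
  if (!any(keep)) stop("no landmarks found for the requested index set")
  lms$points[keep, , drop = FALSE]
}

#' Resize an image for landmark detection
#'
#' Produces the fixed-width representation fed to the landmark detector and
#' the scale factor mapping it back to the original image. Images narrower
#' than the target width are passed through unchanged (no upscaling). The
#' aspect ratio is preserved: the same scale applies to x and y.
#'
#' @param raster RGB or grayscale raster on the 0-255 scale.
#' @param target_width target width in pixels (default 600).
#' @return list with `raster` (the resized image) and `scale`
#'   (`s = W / output_width`).
#' @export
resize_for_detection <- function(raster, target_width = 600) {
  stopifnot_raster(raster)
  w <- raster_width(raster); h <- raster_height(raster)
  out_w <- min(target_width, w)
  s <- w / out_w
  if (s == 1) return(list(raster = raster, scale = 1))
  out_h <- max(1L, as.integer(round(h / s)))
  H <- diag(3) / s; H[3, 3] <- 1  # original -> resized scale map
  list(raster = warp_image(raster, H, target_shape = c(out_h, out_w),
                           interpolation = "bilinear"),
       scale = s)
}

#' Map landmark coordinates from the resized to the original frame
#'
#' @param lms `landmark_set` in the resized frame.
#' @param s scale factor from [resize_for_detection()].
#' @return `landmark_set` in the original frame.
#' @export
rescale_points <- function(lms, s) {
  if (s <= 0) stop("scale must be positive")
  if (lms$frame != "resized")
    stop("rescale_points expects landmarks in the resized frame")
  landmark_set(lms$points * s, frame = "original",
               width = lms$width * s, height = lms$height * s)
}

#' Axis-aligned periocular ROI box
#'
#' @param x0,y0,x1,y1 integer box bounds, half-open, original-image frame.
#' @param margin margin (px, in the landmark frame) used to build the box.
#' @return object of class `roi_box` with `origin` = `c(x0, y0)`.
#' @export
roi_box <- function(x0, y0, x1, y1, margin = 0) {
  if (!(x0 < x1 && y0 < y1)) stop("degenerate ROI box")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1),
                 margin = margin, origin = c(as.integer(x0), as.integer(y0))),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box [%d,%d) x [%d,%d), margin=%g>\n",
              x$x0, x$x1, x$y0, x$y1, x$margin))
  invisible(x)
}

roi_shape <- function(box) c(box$y1 - box$y0, box$x1 - box$x0)

# Margin-expanded bounds of a point cloud, scaled into the original frame.
# Mins are floored and maxes ceiled so no landmark is lost to rounding;
# the box is then clipped to the image bounds.
bounds_to_box <- function(pts, margin, s, img_w, img_h) {
  if (margin < 0) stop("margin must be >= 0")
  rx <- range(pts[, 1]); ry <- range(pts[, 2])
  if (diff(rx) == 0 && diff(ry) == 0)
    stop("degenerate point cloud: all landmarks identical")
  x0 <- floor(s * (rx[1] - margin)); x1 <- ceiling(s * (rx[2] + margin))
  y0 <- floor(s * (ry[1] - margin)); y1 <- ceiling(s * (ry[2] + margin))
  if (x1 <= 0 || y1 <= 0 || x0 >= img_w || y0 >= img_h)
    stop("ROI box falls entirely outside the image")
  roi_box(max(x0, 0), max(y0, 0), min(x1, img_w), min(y1, img_h),
          margin = margin)
}

#' Extract the margin-expanded periocular ROI for one eye
#'
#' Computes the smallest axis-aligned rectangle containing the eye's
#' periocular landmarks, expands it by `margin` on every side (in the
#' landmark frame), maps the bounds to the original image frame with the
#' resize scale, and crops.
#'
#' @param lms `landmark_set` in the resized or original frame.
#' @param eye eye index, 1 or 2.
#' @param margin margin in pixels, interpreted in `lms`'s frame.
#' @param raster original-resolution image.
#' @param topology periocular index configuration.
#' @return list with `box` (`roi_box`) and `raster` (the crop).
#' @export
extract_roi <- function(lms, eye, margin = 10, raster,
                        topology = periocular_topology()) {
  stopifnot_raster(raster)
  pts <- lm_subset(lms, topology$periocular[[eye]])
  s <- landmark_scale(lms, raster)
  box <- bounds_to_box(pts, margin, s,
                       raster_width(raster), raster_height(raster))
  list(box = box, raster = crop_raster(raster, box))
}

#' Combined ROI over the union of both eyes' landmark sets
#'
#' Equals [extract_roi()] applied to the union of the two periocular point
#' clouds with the same margin expansion.
#'
#' @inheritParams extract_roi
#' @export
combined_roi <- function(lms, margin = 10, raster,
                         topology = periocular_topology()) {
  stopifnot_raster(raster)
  pts <- rbind(lm_subset(lms, topology$periocular[[1]]),
               lm_subset(lms, topology$periocular[[2]]))
  s <- landmark_scale(lms, raster)
  box <- bounds_to_box(pts, margin, s,
                       raster_width(raster), raster_height(raster))
  list(box = box, raster = crop_raster(raster, box))
}

landmark_scale <- function(lms, raster) {
  switch(lms$frame,
    original = 1,
    resized = raster_width(raster) / lms$width,
    stop("landmarks must be in the resized or original frame")
  )
}

crop_raster <- function(raster, box) {
  if (length(dim(raster)) == 3L)
    raster[(box$y0 + 1):box$y1, (box$x0 + 1):box$x1, , drop = FALSE]
  else
    raster[(box$y0 + 1):box$y1, (box$x0 + 1):box$x1, drop = FALSE]
}

#' Map points between the original frame and ROI-local coordinates
#'
#' `to_local` subtracts the ROI origin; `from_local` adds it back, so the
#' round trip is exact.
#'
#' @param pts two-column (x, y) matrix or a single `c(x, y)` point.
#' @param box `roi_box`.
#' @return matrix (or point) in the other frame.
#' @export
to_local <- function(pts, box) {
  pts <- rbind(pts)
  sweep(pts, 2, box$origin)
}

#' @rdname to_local
#' @export
from_local <- function(pts, box) {
  pts <- rbind(pts)
  sweep(pts, 2, box$origin, "+")
}

#' Eyebrow geometry: support polygon and reference height
#'
#' The eyebrow height `h` — the vertical extent of the eyebrow landmark
#' polygon's bounding box in the original frame — is the reference
#' dimension from which the trimap offset, morphological kernel sizes and
#' component-retention thresholds are derived, keeping the measurement
#' scale-invariant across subjects.
#'
#' @inheritParams extract_roi
#' @return list with `polygon` (ordered point matrix, original frame) and
#'   `height` (px).
#' @export
eyebrow_geometry <- function(lms, eye, topology = periocular_topology()) {
  if (lms$frame != "original")
    stop("eyebrow_geometry expects landmarks in the original frame")
  poly <- lm_subset(lms, topology$eyebrow[[eye]])
  if (nrow(poly) < 2L) stop("eyebrow landmark set too small")
  h <- diff(range(poly[, 2]))
  if (h <= 0) stop("degenerate eyebrow geometry: zero height")
  list(polygon = poly, height = h)
}
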