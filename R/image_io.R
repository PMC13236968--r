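#' Read an image file as an 8-bit raster array
#'
#' Reads PNG, TIFF or JPEG into the package's raster convention: a numeric
#' array `H x W x 3` (or `H x W` for single-channel images) with values on
#' the `[0, 255]` scale.
#'
#' @param path image file path; format chosen by extension.
#' @return numeric array on the 0-255 scale.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image extension: ", ext)
  )
  if (length(dim(raw)) == 3L && dim(raw)[3] >= 3L) raw <- raw[, , 1:3, drop = FALSE]
  raw * 255
}

#' Write a raster array as PNG
#'
#' @param raster numeric array on the 0-255 scale (`H x W` or `H x W x 3`).
#' @param path output path.
#' @export
write_image <- function(raster, path) {
  png::writePNG(pmin(pmax(raster, 0), 255) / 255, path)
  invisible(path)
}

#' Luminance (HSV value channel) of an RGB raster
#'
#' V = max(R, G, B) per pixel, the hexcone-model value channel on the
#' 0-255 scale. Grayscale rasters are returned unchanged.
#'
#' @param raster RGB raster (`H x W x 3`) or grayscale matrix.
#' @return `H x W` matrix of luminance values.
#' @export
luminance_v <- function(raster) {
  if (length(dim(raster)) == 2L) return(raster)
  pmax(raster[, , 1], raster[, , 2], raster[, , 3])
}

raster_width <- function(raster) dim(raster)[2]
raster_height <- function(raster) dim(raster)[1]

stopifnot_raster <- function(raster) {
  if (is.null(dim(raster)) || length(raster) == 0L)
    stop("invalid input: empty raster")
  invisible(TRUE)
}
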