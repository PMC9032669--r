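#' @keywords internal
"_PACKAGE"

# Raster conventions used throughout the package:
#  * RGB images are m x n x 3 numeric arrays, channel values integers in [0, 255],
#    dim 1 = image rows (top to bottom), dim 2 = columns (left to right).
#  * HSV images are m x n x 3 arrays with H integer in [0, 180), S and V in [0, 255]
#    (the byte-range hue convention common in vision toolkits).
#  * Grayscale images are m x n matrices with integers in [0, 255].
#  * Binary masks are m x n matrices with values in {0, 255}.

#' Validate an RGB image array
#'
#' Checks that `img` is an `m x n x 3` array with all channel values inside
#' `[0, 255]`, and returns it invisibly.
#'
#' @param img an array to validate.
#' @return `img`, invisibly.
#' @export
validate_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("RGB image must be an m x n x 3 array")
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop("RGB image must have positive dimensions")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("RGB channel values must lie in [0, 255]")
  invisible(img)
}

#' Validate a binary mask
#'
#' A mask is an `m x n` matrix whose only values are 0 (background) and 255
#' (foreground).
#'
#' @param mask a matrix to validate.
#' @return `mask`, invisibly.
#' @export
validate_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!all(mask %in% c(0, 255))) stop("mask values must be 0 or 255")
  invisible(mask)
}

#' Read an RGB image from a PNG file
#'
#' @param path path to a PNG file.
#' @return an RGB image array (integers in `[0, 255]`).
#' @export
read_image_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  round(px * 255)
}

#' Write an RGB image to a PNG file
#'
#' @param img RGB image array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  validate_rgb(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read a binary mask from a single-channel PNG
#'
#' Any pixel above 127 is treated as foreground.
#'
#' @param path path to a PNG file.
#' @return a `{0, 255}` mask matrix.
#' @export
read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  ifelse(px > 0.5, 255, 0)
}

#' Write a binary mask as a single-channel PNG
#'
#' @param mask `{0, 255}` mask matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  validate_mask(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}
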