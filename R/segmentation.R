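# Vegetation segmentation: RGB -> HSV -> inclusive band threshold -> binary mask,
# then morphological clean-up with a structuring element.

#' Convert an RGB image to HSV
#'
#' Performs the standard per-pixel RGB to HSV conversion and rescales the
#' channels to the byte-range convention used by the segmentation thresholds:
#' hue as an integer in `[0, 180)` (degrees halved), saturation and value as
#' integers in `[0, 255]`.
#'
#' @param img RGB image array (`m x n x 3`, values in `[0, 255]`).
#' @return HSV image array of the same dimensions.
#' @export
rgb_to_hsv <- function(img) {
  validate_rgb(img)
  d <- dim(img)
  rgb <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  out <- array(0, d)
  out[, , 1] <- round(hsv[1, ] * 180) %% 180
  out[, , 2] <- round(hsv[2, ] * 255)
  out[, , 3] <- round(hsv[3, ] * 255)
  out
}

#' HSV threshold band for vegetation
#'
#' Bundles the lower/upper bounds on hue, saturation and value that define
#' "green vegetation" against soil. The defaults were tuned for field images
#' under varying illumination; hue uses the `[0, 180)` byte-range scale.
#'
#' @param hl,hh hue bounds (integers in `[0, 180)`).
#' @param sl,sh saturation bounds (integers in `[0, 255]`).
#' @param vl,vh value bounds (integers in `[0, 255]`).
#' @return an object of class `hsv_thresholds`.
#' @export
hsv_thresholds <- function(hl = 33, hh = 95, sl = 34, sh = 255, vl = 60, vh = 250) {
  th <- list(hl = hl, hh = hh, sl = sl, sh = sh, vl = vl, vh = vh)
  if (hl > hh || sl > sh || vl > vh)
    stop("invalid thresholds: each lower bound must not exceed its upper bound")
  structure(th, class = "hsv_thresholds")
}

#' Threshold an HSV image into a vegetation mask
#'
#' A pixel is foreground (255) iff all three channels lie inside their bands,
#' bounds inclusive; otherwise background (0).
#'
#' @param hsv HSV image array (see [rgb_to_hsv()]).
#' @param th an [hsv_thresholds()] object.
#' @return a `{0, 255}` mask matrix.
#' @export
threshold_vegetation <- function(hsv, th = hsv_thresholds()) {
  stopifnot(inherits(th, "hsv_thresholds"))
  h <- hsv[, , 1]; s <- hsv[, , 2]; v <- hsv[, , 3]
  inside <- h >= th$hl & h <= th$hh & s >= th$sl & s <= th$sh & v >= th$vl & v <= th$vh
  out <- ifelse(inside, 255, 0)
  matrix(out, dim(hsv)[1], dim(hsv)[2])
}

#' Structuring element for morphological operations
#'
#' @param size odd side length in pixels (default 5).
#' @param shape `"box"` (solid square, the default) or `"disc"`.
#' @return a `{0, 1}` matrix usable as a morphology kernel.
#' @export
structuring_element <- function(size = 5, shape = c("box", "disc")) {
  shape <- match.arg(shape)
  if (size %% 2 == 0) stop("structuring element size must be odd")
  EBImage::makeBrush(size, shape = shape)
}

as_binary01 <- function(mask) {
  validate_mask(mask)
  (mask > 0) * 1
}

# EBImage's morphology replicates edge values outside the image; the set
# definition used here treats everything outside as background. Zero-padding
# by the element radius before the call restores that convention.
morph_with_background_border <- function(mask, se, op) {
  r <- (nrow(se) - 1) / 2
  m <- nrow(mask); n <- ncol(mask)
  padded <- matrix(0, m + 2 * r, n + 2 * r)
  padded[r + seq_len(m), r + seq_len(n)] <- as_binary01(mask)
  out <- op(padded, se)
  unclass(out)[r + seq_len(m), r + seq_len(n)] * 255
}

#' Morphological erosion of a binary mask
#'
#' The output keeps a pixel iff the structuring element, centred there, fits
#' entirely inside the foreground (pixels outside the image count as
#' background).
#'
#' @param mask `{0, 255}` mask matrix.
#' @param se structuring element from [structuring_element()].
#' @return eroded `{0, 255}` mask.
#' @export
morph_erode <- function(mask, se = structuring_element()) {
  morph_with_background_border(mask, se, EBImage::erode)
}

#' Morphological dilation of a binary mask
#'
#' @inheritParams morph_erode
#' @return dilated `{0, 255}` mask.
#' @export
morph_dilate <- function(mask, se = structuring_element()) {
  morph_with_background_border(mask, se, EBImage::dilate)
}

#' Morphological opening (erosion then dilation)
#'
#' Removes foreground structures smaller than the structuring element and
#' smooths contours, without growing the remaining objects.
#'
#' @inheritParams morph_erode
#' @return opened `{0, 255}` mask.
#' @export
morph_open <- function(mask, se = structuring_element()) {
  morph_dilate(morph_erode(mask, se), se)
}

#' Morphological closing (dilation then erosion)
#'
#' Fills holes and gaps smaller than the structuring element without shrinking
#' the objects.
#'
#' @inheritParams morph_erode
#' @return closed `{0, 255}` mask.
#' @export
morph_close <- function(mask, se = structuring_element()) {
  morph_erode(morph_dilate(mask, se), se)
}

#' Clean a vegetation mask by opening then closing
#'
#' The standard enhancement applied after thresholding: opening removes
#' salt noise and small spurious regions, closing then fills small holes
#' inside the surviving plant silhouettes. Both use the same structuring
#' element (5x5 solid square by default).
#'
#' @inheritParams morph_erode
#' @return cleaned `{0, 255}` mask.
#' @export
enhance_mask <- function(mask, se = structuring_element()) {
  morph_close(morph_open(mask, se), se)
}
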