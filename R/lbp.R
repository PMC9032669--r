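# Rotation-invariant uniform local binary patterns (riu2).
#
# For a center pixel with gray value g_c and P neighbours g_0..g_{P-1} sampled
# on a circle of radius R (p = 0 due east, proceeding counter-clockwise), the
# bit pattern is b_p = s(g_p - g_c) with s(x) = 1 for x >= 0. The plain LBP
# code is sum b_p 2^p. The riu2 descriptor maps "uniform" patterns (at most
# two circular 0<->1 transitions) to their count of ones and every other
# pattern to the shared bin P + 1, giving P + 2 bins in total. The mapping is
# invariant to circular shifts of the pattern, hence to image rotation, and to
# any monotone gray-level transformation.

#' Convert an RGB image to grayscale
#'
#' Luma-weighted conversion (ITU-R BT.601 weights by default), rounded to
#' integers in `[0, 255]`.
#'
#' @param img RGB image array.
#' @param weights length-3 channel weights summing to 1.
#' @return a grayscale matrix.
#' @export
to_grayscale <- function(img, weights = c(0.299, 0.587, 0.114)) {
  validate_rgb(img)
  stopifnot(length(weights) == 3)
  round(img[, , 1] * weights[1] + img[, , 2] * weights[2] + img[, , 3] * weights[3])
}

#' LBP configuration
#'
#' Bundles the neighbourhood resolution `(P, R)`, the square size patches are
#' resized to, and the cell size of the grid over which per-cell histograms
#' are concatenated. Supported resolutions are `(8,1)`, `(16,2)`, `(24,3)`.
#'
#' @param p neighbour count: 8, 16 or 24.
#' @param r circle radius in pixels: 1, 2 or 3 (paired with `p`).
#' @param image_size side length patches are resized to (256, 128 or 64).
#' @param cell_size side length of the grid cells; must divide `image_size`,
#'   be smaller than it, and exceed `2r` so each cell has interior centers.
#' @param normalize L1-normalize each cell histogram (default `TRUE`).
#' @return an object of class `lbp_config`.
#' @export
lbp_config <- function(p = 8, r = 1, image_size = 256, cell_size = 32,
                       normalize = TRUE) {
  ok <- list(c(8, 1), c(16, 2), c(24, 3))
  if (!any(vapply(ok, function(z) all(z == c(p, r)), logical(1))))
    stop("(p, r) must be one of (8,1), (16,2), (24,3)")
  if (image_size %% cell_size != 0) stop("cell_size must divide image_size")
  if (cell_size >= image_size) stop("cell_size must be smaller than image_size")
  if (cell_size <= 2 * r) stop("cell_size must exceed 2*r")
  structure(list(p = as.integer(p), r = r, image_size = as.integer(image_size),
                 cell_size = as.integer(cell_size), normalize = isTRUE(normalize)),
            class = "lbp_config")
}

#' Fingerprint of an LBP configuration
#'
#' A short string identifying the feature space; stored inside trained models
#' so a model cannot be applied to features from a different configuration.
#'
#' @param cfg an `lbp_config`.
#' @return a character scalar.
#' @export
lbp_fingerprint <- function(cfg) {
  stopifnot(inherits(cfg, "lbp_config"))
  sprintf("lbp-p%d-r%g-img%d-cell%d-%s", cfg$p, cfg$r, cfg$image_size,
          cfg$cell_size, if (cfg$normalize) "l1" else "raw")
}

# Row/column offsets of the P neighbours. For (8,1) the classic 3x3 lattice is
# used (diagonals at distance 1, no interpolation); otherwise exact circle
# coordinates, sampled with bilinear interpolation. Image rows grow downward,
# so counter-clockwise means the row offset is -R*sin(theta).
neighbor_offsets <- function(p, r) {
  theta <- 2 * pi * (0:(p - 1)) / p
  dr <- -r * sin(theta)
  dc <- r * cos(theta)
  if (p == 8 && r == 1) {
    dr <- round(dr); dc <- round(dc)
  } else {
    dr <- ifelse(abs(dr - round(dr)) < 1e-9, round(dr), dr)
    dc <- ifelse(abs(dc - round(dc)) < 1e-9, round(dc), dc)
  }
  cbind(dr = dr, dc = dc)
}

bilinear_at <- function(gray, rr, cc) {
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  r1 <- pmin(r0 + 1, nrow(gray)); c1 <- pmin(c0 + 1, ncol(gray))
  gray[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    gray[cbind(r1, c0)] * fr * (1 - fc) +
    gray[cbind(r0, c1)] * (1 - fr) * fc +
    gray[cbind(r1, c1)] * fr * fc
}

#' Sample the circular neighbourhood of a pixel
#'
#' Returns the P gray values `g_0..g_{P-1}` on the circle of radius R around
#' `center`, starting due east and proceeding counter-clockwise. Non-integer
#' sample coordinates are bilinearly interpolated; for `(P, R) = (8, 1)` the
#' classic 3x3 lattice neighbours are used directly.
#'
#' @param gray grayscale matrix.
#' @param center `c(row, col)` of the center pixel.
#' @param p neighbour count.
#' @param r radius in pixels.
#' @return numeric vector of length `p`.
#' @export
circular_neighbors <- function(gray, center, p = 8, r = 1) {
  b <- ceiling(r)
  if (center[1] <= b || center[1] > nrow(gray) - b ||
      center[2] <= b || center[2] > ncol(gray) - b)
    stop("center too close to the image border for radius ", r)
  off <- neighbor_offsets(p, r)
  bilinear_at(gray, center[1] + off[, "dr"], center[2] + off[, "dc"])
}

#' Threshold a neighbourhood against its center value
#'
#' `b_p = 1` iff `g_p >= g_c` (ties count as 1).
#'
#' @param g_c center gray value.
#' @param neighbors numeric vector of neighbour gray values.
#' @return integer 0/1 vector of the same length.
#' @export
binary_pattern <- function(g_c, neighbors) {
  as.integer(neighbors - g_c >= 0)
}

#' Plain LBP code of a bit pattern
#'
#' The weighted sum `sum b_p 2^p`, `b_0` carrying weight 1.
#'
#' @param pattern integer 0/1 vector, `b_0` first.
#' @return integer in `[0, 2^P - 1]`.
#' @export
lbp_code <- function(pattern) {
  stopifnot(all(pattern %in% c(0L, 1L)))
  sum(pattern * 2^(seq_along(pattern) - 1))
}

#' Circular uniformity measure of a bit pattern
#'
#' Number of 0/1 transitions around the circle, including the wrap-around
#' pair `(b_{P-1}, b_0)`.
#'
#' @param pattern integer 0/1 vector.
#' @return non-negative even integer.
#' @export
uniformity <- function(pattern) {
  stopifnot(all(pattern %in% c(0L, 1L)))
  sum(abs(diff(c(pattern, pattern[1]))))
}

#' Rotation-invariant uniform code of a bit pattern
#'
#' Uniform patterns (uniformity at most 2) map to their count of ones
#' (0..P); all other patterns map to the shared bin `P + 1`.
#'
#' @param pattern integer 0/1 vector.
#' @return integer in `[0, P + 1]`.
#' @export
riu2_code <- function(pattern) {
  if (uniformity(pattern) <= 2) sum(pattern) else length(pattern) + 1L
}

# Vectorized riu2 code image over all valid interior centers.
# Returns an integer matrix of size (m - 2b) x (n - 2b), b = ceiling(r).
riu2_code_image <- function(gray, p, r) {
  b <- ceiling(r)
  m <- nrow(gray); n <- ncol(gray)
  if (m <= 2 * b || n <= 2 * b)
    stop("image too small to contain any valid center for radius ", r)
  rr <- (b + 1):(m - b)
  cc <- (b + 1):(n - b)
  gc <- gray[rr, cc, drop = FALSE]
  off <- neighbor_offsets(p, r)
  bits <- vector("list", p)
  for (k in seq_len(p)) {
    dr <- off[k, "dr"]; dc <- off[k, "dc"]
    if (dr == round(dr) && dc == round(dc)) {
      gp <- gray[rr + dr, cc + dc, drop = FALSE]
    } else {
      r0 <- floor(dr); c0 <- floor(dc); fr <- dr - r0; fc <- dc - c0
      gp <- gray[rr + r0, cc + c0, drop = FALSE] * (1 - fr) * (1 - fc) +
        gray[rr + r0 + 1, cc + c0, drop = FALSE] * fr * (1 - fc) +
        gray[rr + r0, cc + c0 + 1, drop = FALSE] * (1 - fr) * fc +
        gray[rr + r0 + 1, cc + c0 + 1, drop = FALSE] * fr * fc
    }
    bits[[k]] <- (gp - gc >= -1e-6) * 1L   # tolerance keeps exact ties at 1
  }
  ones <- Reduce(`+`, bits)
  u <- abs(bits[[1]] - bits[[p]])
  for (k in 2:p) u <- u + abs(bits[[k]] - bits[[k - 1]])
  codes <- ones
  codes[u > 2] <- p + 1L
  codes
}

#' riu2 histogram of a grayscale image
#'
#' Computes the riu2 code of every valid interior pixel (a border of width
#' `ceiling(r)` is excluded) and bins the codes into `p + 2` bins `0..p+1`,
#' L1-normalized.
#'
#' @param gray grayscale matrix, both sides larger than `2*ceiling(r)`.
#' @param p neighbour count.
#' @param r radius.
#' @param normalize L1-normalize (default `TRUE`).
#' @return numeric vector of length `p + 2`.
#' @export
riu2_histogram <- function(gray, p = 8, r = 1, normalize = TRUE) {
  codes <- riu2_code_image(gray, p, r)
  h <- tabulate(as.vector(codes) + 1L, nbins = p + 2L)
  if (normalize) h <- h / sum(h)
  h
}

#' Concatenated per-cell riu2 features
#'
#' Partitions a square grayscale image of side `cfg$image_size` into the
#' `(image_size / cell_size)^2` non-overlapping cells in raster order (cell
#' rows top to bottom, then cell columns left to right), computes the riu2
#' histogram of each cell, and concatenates them.
#'
#' @param gray square grayscale matrix of side `cfg$image_size`.
#' @param cfg an [lbp_config()].
#' @return numeric feature vector of length `n_cells * (p + 2)`.
#' @export
cell_grid_features <- function(gray, cfg) {
  stopifnot(inherits(cfg, "lbp_config"))
  if (!all(dim(gray) == cfg$image_size))
    stop("image must already be resized to ", cfg$image_size, " x ", cfg$image_size)
  k <- cfg$image_size %/% cfg$cell_size
  feats <- vector("list", k * k)
  i <- 1L
  for (cr in seq_len(k)) {
    rows <- ((cr - 1L) * cfg$cell_size + 1L):(cr * cfg$cell_size)
    for (cc in seq_len(k)) {
      cols <- ((cc - 1L) * cfg$cell_size + 1L):(cc * cfg$cell_size)
      feats[[i]] <- riu2_histogram(gray[rows, cols, drop = FALSE],
                                   cfg$p, cfg$r, normalize = cfg$normalize)
      i <- i + 1L
    }
  }
  unlist(feats, use.names = FALSE)
}

#' Resize a grayscale image
#'
#' Bilinear resize to a square of side `size` (direct stretch). With
#' `preserve_aspect = TRUE` the image is instead scaled to fit and padded
#' symmetrically with its mean gray value.
#'
#' @param gray grayscale matrix.
#' @param size target side length.
#' @param preserve_aspect pad instead of stretching (default `FALSE`).
#' @return a `size x size` grayscale matrix.
#' @export
resize_gray <- function(gray, size, preserve_aspect = FALSE) {
  if (any(dim(gray) == 0)) stop("degenerate (zero-area) image")
  if (preserve_aspect) {
    s <- size / max(dim(gray))
    h <- max(1L, round(nrow(gray) * s)); w <- max(1L, round(ncol(gray) * s))
    core <- EBImage::resize(gray, w = h, h = w)
    out <- matrix(round(mean(gray)), size, size)
    r0 <- (size - h) %/% 2L; c0 <- (size - w) %/% 2L
    out[r0 + seq_len(h), c0 + seq_len(w)] <- core
    return(pmin(pmax(round(out), 0), 255))
  }
  out <- EBImage::resize(gray, w = size, h = size)
  pmin(pmax(round(unclass(out)), 0), 255)
}

#' Full texture descriptor of an ROI patch
#'
#' Grayscale conversion, bilinear resize to `cfg$image_size`, then
#' [cell_grid_features()].
#'
#' @param patch an `roi_patch` (from [extract_patches()]) or an RGB array.
#' @param cfg an [lbp_config()].
#' @param preserve_aspect passed to [resize_gray()].
#' @return numeric feature vector.
#' @export
featurize_patch <- function(patch, cfg, preserve_aspect = FALSE) {
  rgb <- if (inherits(patch, "roi_patch")) patch$pixels else patch
  validate_rgb(rgb)
  gray <- resize_gray(to_grayscale(rgb), cfg$image_size, preserve_aspect)
  cell_grid_features(gray, cfg)
}

#' Featurize a list of patches into a data frame
#'
#' @param patches list of `roi_patch` objects or RGB arrays.
#' @param cfg an [lbp_config()].
#' @param labels optional character vector of class labels.
#' @param ids optional patch identifiers (default `patch_1..patch_n`).
#' @return a data frame with columns `patch_id`, `label`, `f_0..f_{d-1}`.
#' @export
featurize_patches <- function(patches, cfg, labels = NULL, ids = NULL) {
  feats <- t(vapply(patches, featurize_patch, cfg = cfg,
                    FUN.VALUE = numeric(feature_length(cfg))))
  colnames(feats) <- paste0("f_", seq_len(ncol(feats)) - 1L)
  if (is.null(ids)) ids <- paste0("patch_", seq_along(patches))
  if (is.null(labels)) labels <- rep(NA_character_, length(patches))
  cbind(data.frame(patch_id = ids, label = labels, stringsAsFactors = FALSE),
        as.data.frame(feats))
}

#' Length of the concatenated feature vector
#'
#' `(image_size / cell_size)^2 * (p + 2)`.
#'
#' @param cfg an [lbp_config()].
#' @return integer feature dimension.
#' @export
feature_length <- function(cfg) {
  as.integer((cfg$image_size %/% cfg$cell_size)^2 * (cfg$p + 2L))
}
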