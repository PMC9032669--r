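# Synthetic multi-plant field scenes with ground truth.
#
# The generator emulates what the pipeline actually relies on in early-growth
# field imagery: a brownish, textured soil background whose hue lies outside
# the vegetation band; green plants whose hue/saturation/value stay inside
# it; class-distinct leaf geometry and surface texture (wide sparsely-veined
# blades for the crop, thin densely-veined blades for narrow-leaf weeds,
# lobed blotchy-textured leaves for broadleaf weeds); global illumination
# gain; additive sensor noise; and non-overlapping plant placement (the
# early-growth assumption under which one connected region is one plant).

#' Parameters of a synthetic field scene
#'
#' @param size scene side length in pixels (default 768).
#' @param per_class named or unnamed counts of plants for Crop, NLW, BLW
#'   (default 3 each).
#' @param scale_range plant diameter range in pixels (default 60-110).
#' @param min_separation minimum gap between plant bounding boxes in pixels
#'   (default 30, comfortably above the 5x5 structuring element).
#' @param soil_rgb soil base colour (default a dry brown).
#' @param soil_noise amplitude of uniform soil colour noise (default 12).
#' @param gain_range multiplicative illumination gain range (default
#'   0.9-1.1, emulating sunny/cloudy capture).
#' @param noise_sd additive Gaussian sensor noise sd (default 2).
#' @param stripe_overlap 0 keeps Crop and NLW vein spacings well separated;
#'   values toward 1 pull them together, emulating the monocot texture
#'   confusion observed in real fields.
#' @param seed RNG seed; every random choice in the scene flows from it.
#' @return a list of class `scene_params`.
#' @export
scene_params <- function(size = 768, per_class = c(Crop = 3, NLW = 3, BLW = 3),
                         scale_range = c(60, 110), min_separation = 30,
                         soil_rgb = c(118, 86, 58), soil_noise = 12,
                         gain_range = c(0.9, 1.1), noise_sd = 2,
                         stripe_overlap = 0, seed = 1) {
  if (is.null(names(per_class))) names(per_class) <- WEED_CLASSES
  stopifnot(all(per_class >= 0), min_separation >= 0, all(gain_range > 0),
            stripe_overlap >= 0, stripe_overlap <= 1)
  structure(list(size = as.integer(size), per_class = per_class,
                 scale_range = scale_range, min_separation = min_separation,
                 soil_rgb = soil_rgb, soil_noise = soil_noise,
                 gain_range = gain_range, noise_sd = noise_sd,
                 stripe_overlap = stripe_overlap, seed = as.integer(seed)),
            class = "scene_params")
}

hsv_to_rgb255 <- function(h, s, v) {
  # h in [0,180), s,v in [0,255] -> 3 x n matrix of RGB in [0,255]
  grDevices::col2rgb(grDevices::hsv(pmin(h / 180, 0.9999), s / 255, v / 255))
}

# Vein spacing as a fraction of plant diameter: a blade carries a roughly
# fixed number of veins, so spacing scales with plant size and the texture
# frequency seen after patch resizing is scale-invariant. stripe_overlap
# pulls the Crop and NLW bands together.
vein_spacing <- function(cls, overlap) {
  base <- switch(cls, Crop = c(0.075, 0.100), NLW = c(0.035, 0.047),
                 BLW = c(0, 0))
  mid <- c(0.055, 0.062)
  base + overlap * (mid - base)
}

#' Render one synthetic plant
#'
#' Draws a single plant on a transparent square canvas and returns its RGB
#' patch together with its support mask. Crop and NLW plants are rosettes of
#' elongated elliptical blades with longitudinal vein stripes (wide blades
#' with sparse veins for Crop, thin blades with dense veins for NLW); BLW
#' plants are lobed blobs with a blotchy surface texture. All rendered pixels
#' keep their HSV values inside the default vegetation threshold band even
#' after the scene-level illumination gain.
#'
#' @param cls `"Crop"`, `"NLW"` or `"BLW"`.
#' @param scale plant diameter in pixels (>= 24).
#' @param seed RNG seed.
#' @param stripe_overlap see [scene_params()].
#' @return a list with `patch` (RGB array with background zeros), `mask`
#'   (logical matrix) and `class`.
#' @export
render_plant <- function(cls, scale = 80, seed = 1, stripe_overlap = 0) {
  cls <- match.arg(cls, WEED_CLASSES)
  if (scale < 24) stop("degenerate plant scale (need >= 24 px)")
  old <- .Random.seed_save()
  set.seed(seed)
  s <- as.integer(round(scale))
  ctr <- (s + 1) / 2
  rr <- matrix(seq_len(s), s, s)          # row coordinate
  cc <- matrix(seq_len(s), s, s, byrow = TRUE)
  u0 <- rr - ctr; v0 <- cc - ctr
  mask <- matrix(FALSE, s, s)
  tex <- matrix(0, s, s)                  # in [-1, 1], value modulation field

  if (cls %in% c("Crop", "NLW")) {
    n_blades <- if (cls == "Crop") sample(4:6, 1) else sample(7:10, 1)
    len <- s * 0.47
    # blade half-widths: wide for Crop, narrow for NLW, but never thinner than
    # the 5x5 clean-up element can preserve (real leaves at this resolution
    # are wider than the structuring element)
    wid <- if (cls == "Crop") max(s * stats::runif(1, 0.085, 0.115), 3.5) else
      max(s * stats::runif(1, 0.042, 0.058), 3.0)
    sp <- vein_spacing(cls, stripe_overlap)
    spacing <- s * stats::runif(1, sp[1], sp[2])
    ang0 <- stats::runif(1, 0, 2 * pi)
    mask <- mask | ((u0^2 + v0^2) <= (0.10 * s)^2)   # rosette crown keeps blades connected
    for (kb in seq_len(n_blades)) {
      ang <- ang0 + 2 * pi * (kb - 1) / n_blades + stats::rnorm(1, 0, 0.12)
      a <- u0 * cos(ang) + v0 * sin(ang)       # along the blade
      b <- -u0 * sin(ang) + v0 * cos(ang)      # across the blade
      inside <- ((a - len / 2)^2 / (len / 2)^2 + b^2 / wid^2) <= 1
      mask <- mask | inside
      # longitudinal veins: stripes across the blade width
      tex[inside] <- sin(2 * pi * b[inside] / spacing)
    }
  } else {
    n_lobes <- sample(5:7, 1)
    phase <- stats::runif(1, 0, 2 * pi)
    theta <- atan2(v0, u0)
    rad <- sqrt(u0^2 + v0^2)
    rmax <- (s / 2 - 1) * (0.62 + 0.30 * abs(cos(n_lobes * theta / 2 + phase)))
    mask <- rad <= rmax
    # blotchy texture: thresholded smoothed noise
    z <- matrix(stats::rnorm(s * s), s, s)
    for (i in 1:3) z <- box_blur(z)
    tex <- pmax(pmin(z / stats::sd(z), 1), -1)
  }

  hue <- stats::runif(1, 45, 75)
  sat <- stats::runif(1, 160, 215)
  val <- stats::runif(1, 125, 165)
  v_px <- val + 38 * tex + stats::rnorm(s * s, 0, 2)
  v_px <- pmin(pmax(v_px, 72), 212)              # stays in [60,250]/gain band
  h_px <- pmin(pmax(hue + stats::rnorm(s * s, 0, 1.5), 37), 91)
  s_px <- pmin(pmax(sat + stats::rnorm(s * s, 0, 6), 60), 250)
  rgbm <- hsv_to_rgb255(h_px, s_px, v_px)
  patch <- array(0, c(s, s, 3))
  for (k in 1:3) {
    ch <- matrix(rgbm[k, ], s, s)
    ch[!mask] <- 0
    patch[, , k] <- ch
  }
  .Random.seed_restore(old)
  list(patch = patch, mask = mask, class = cls)
}

box_blur <- function(z) {
  m <- nrow(z); n <- ncol(z)
  p <- rbind(z[1, ], z, z[m, ])
  p <- cbind(p[, 1], p, p[, n])
  (p[1:m, 1:n] + p[1:m, 2:(n + 1)] + p[1:m, 3:(n + 2)] +
     p[2:(m + 1), 1:n] + p[2:(m + 1), 2:(n + 1)] + p[2:(m + 1), 3:(n + 2)] +
     p[3:(m + 2), 1:n] + p[3:(m + 2), 2:(n + 1)] + p[3:(m + 2), 3:(n + 2)]) / 9
}

#' Generate a synthetic field scene
#'
#' Renders the requested plants, places them without overlap at the requested
#' minimum separation (bounded rejection sampling), composites them over a
#' noisy soil background, applies a global illumination gain and additive
#' sensor noise, and returns the scene with its ground-truth manifest.
#'
#' @param params a [scene_params()] object.
#' @return an object of class `field_scene`: a list with `image` (RGB array),
#'   `plants` (list with per-plant `class`, `mask` (full-scene logical),
#'   `bbox`, `centroid`) and `manifest` (data frame).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  old <- .Random.seed_save()
  set.seed(params$seed)
  sz <- params$size
  img <- array(0, c(sz, sz, 3))
  for (k in 1:3)
    img[, , k] <- params$soil_rgb[k] +
      stats::runif(sz * sz, -params$soil_noise, params$soil_noise)

  classes <- rep(names(params$per_class), times = params$per_class)
  plants <- list()
  occupied <- NULL  # rows of (rmin, cmin, rmax, cmax)
  sep <- params$min_separation
  for (i in seq_along(classes)) {
    scale <- stats::runif(1, params$scale_range[1], params$scale_range[2])
    pl <- render_plant(classes[i], scale, seed = params$seed * 1000L + i,
                       stripe_overlap = params$stripe_overlap)
    s <- nrow(pl$mask)
    if (s + 2 > sz) stop("plant larger than the scene")
    placed <- FALSE
    for (try in 1:200) {
      r0 <- sample.int(sz - s - 1, 1)
      c0 <- sample.int(sz - s - 1, 1)
      box <- c(r0, c0, r0 + s - 1, c0 + s - 1)
      clash <- !is.null(occupied) &&
        any(occupied[, 1] <= box[3] + sep & occupied[, 3] >= box[1] - sep &
              occupied[, 2] <= box[4] + sep & occupied[, 4] >= box[2] - sep)
      if (!clash) { placed <- TRUE; break }
    }
    if (!placed)
      stop("infeasible packing: could not place plant ", i,
           " after bounded retries; reduce counts, scale or separation")
    occupied <- rbind(occupied, box)
    full_mask <- matrix(FALSE, sz, sz)
    full_mask[r0:(r0 + s - 1), c0:(c0 + s - 1)] <- pl$mask
    for (k in 1:3) {
      sub <- img[r0:(r0 + s - 1), c0:(c0 + s - 1), k]
      sub[pl$mask] <- pl$patch[, , k][pl$mask]
      img[r0:(r0 + s - 1), c0:(c0 + s - 1), k] <- sub
    }
    idx <- which(full_mask, arr.ind = TRUE)
    plants[[i]] <- list(class = classes[i], mask = full_mask,
                        bbox = c(rmin = min(idx[, 1]), cmin = min(idx[, 2]),
                                 rmax = max(idx[, 1]), cmax = max(idx[, 2])),
                        centroid = c(row = mean(idx[, 1]), col = mean(idx[, 2])))
  }
  gain <- stats::runif(1, params$gain_range[1], params$gain_range[2])
  img <- img * gain + stats::rnorm(length(img), 0, params$noise_sd)
  img <- round(pmin(pmax(img, 0), 255))
  .Random.seed_restore(old)
  manifest <- if (length(plants) == 0) {
    data.frame(plant_id = integer(0), class = character(0))
  } else {
    do.call(rbind, lapply(seq_along(plants), function(i) {
      p <- plants[[i]]
      data.frame(plant_id = i, class = p$class,
                 centroid_row = p$centroid[1], centroid_col = p$centroid[2],
                 rmin = p$bbox[1], cmin = p$bbox[2],
                 rmax = p$bbox[3], cmax = p$bbox[4], row.names = NULL)
    }))
  }
  structure(list(image = img, plants = plants, manifest = manifest,
                 params = params),
            class = "field_scene")
}

#' Turn scenes into a labeled patch dataset
#'
#' Runs the segmentation pipeline (threshold, enhance, label, area filter) on
#' every scene, matches each extracted ROI to a ground-truth plant by mask
#' intersection-over-union (match requires IoU >= `min_iou`), and returns the
#' labeled patches. Unmatched ROIs are dropped with a warning.
#'
#' @param scenes a `field_scene` or list of them.
#' @param th segmentation thresholds.
#' @param se structuring element.
#' @param min_area component area filter.
#' @param connectivity 4 or 8.
#' @param padding patch padding.
#' @param min_iou minimum intersection-over-union for a match (default 0.5).
#' @return a list with `patches` (list of `roi_patch` with `class` set) and
#'   `labels` (data frame: patch_id, scene, label).
#' @export
scene_to_dataset <- function(scenes, th = hsv_thresholds(),
                             se = structuring_element(), min_area = 400,
                             connectivity = 8, padding = 0, min_iou = 0.5) {
  if (inherits(scenes, "field_scene")) scenes <- list(scenes)
  patches <- list(); labels <- list()
  for (si in seq_along(scenes)) {
    sc <- scenes[[si]]
    mask <- enhance_mask(threshold_vegetation(rgb_to_hsv(sc$image), th), se)
    cm <- filter_small_components(label_components(mask, connectivity), min_area)
    rois <- extract_patches(sc$image, cm, padding)
    for (ri in seq_along(rois)) {
      comp_mask <- cm$labels == cm$components$label[ri]
      ious <- vapply(sc$plants, function(p) {
        inter <- sum(comp_mask & p$mask)
        uni <- sum(comp_mask | p$mask)
        if (uni == 0) 0 else inter / uni
      }, numeric(1))
      if (length(ious) == 0 || max(ious) < min_iou) {
        warning("scene ", si, ": ROI ", ri, " matched no ground-truth plant; dropped")
        next
      }
      pat <- rois[[ri]]
      pat$class <- sc$plants[[which.max(ious)]]$class
      patches[[length(patches) + 1L]] <- pat
      labels[[length(labels) + 1L]] <-
        data.frame(patch_id = sprintf("scene%d_roi%d", si, ri),
                   scene = si, label = pat$class)
    }
  }
  list(patches = patches,
       labels = if (length(labels)) do.call(rbind, labels) else
         data.frame(patch_id = character(0), scene = integer(0),
                    label = character(0)))
}

#' Render a standalone labeled patch set
#'
#' Convenience generator for classifier training: renders plants directly
#' (no scene compositing) and returns patches plus labels.
#'
#' Each plant is imaged under the same camera model as full scenes (noisy
#' soil background, illumination gain, additive sensor noise) and its patch
#' is then extracted through the standard segmentation pipeline (threshold,
#' enhance, connected components, bounding-box crop) — the same protocol
#' that produces ROIs from field images, so training patches follow the
#' deployment distribution.
#'
#' @param per_class named counts per class (default 134/133/133).
#' @param scale_range plant diameter range.
#' @param soil_rgb,soil_noise,gain_range,noise_sd imaging model, as in
#'   [scene_params()].
#' @param th,se,min_area,connectivity extraction pipeline settings, as in
#'   [scene_to_dataset()].
#' @param seed RNG seed.
#' @param stripe_overlap see [scene_params()].
#' @return a list with `patches` (RGB arrays) and `labels`.
#' @export
render_patch_set <- function(per_class = c(Crop = 134, NLW = 133, BLW = 133),
                             scale_range = c(60, 110),
                             soil_rgb = c(118, 86, 58), soil_noise = 12,
                             gain_range = c(0.9, 1.1), noise_sd = 2,
                             th = hsv_thresholds(), se = structuring_element(),
                             min_area = 400, connectivity = 8,
                             seed = 1, stripe_overlap = 0) {
  if (is.null(names(per_class))) names(per_class) <- WEED_CLASSES
  classes <- rep(names(per_class), times = per_class)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  scales <- stats::runif(length(classes), scale_range[1], scale_range[2])
  gains <- stats::runif(length(classes), gain_range[1], gain_range[2])
  noise_seeds <- sample.int(2^31 - 2, length(classes))
  margin <- 16L
  patches <- lapply(seq_along(classes), function(i) {
    pl <- render_plant(classes[i], scales[i], seed = seed * 100000L + i,
                       stripe_overlap = stripe_overlap)
    set.seed(noise_seeds[i])
    s <- nrow(pl$mask)
    cs <- s + 2L * margin
    canvas <- array(0, c(cs, cs, 3))
    for (k in 1:3) {
      ch <- matrix(soil_rgb[k] + stats::runif(cs * cs, -soil_noise, soil_noise),
                   cs, cs)
      sub <- ch[margin + seq_len(s), margin + seq_len(s)]
      sub[pl$mask] <- pl$patch[, , k][pl$mask]
      ch[margin + seq_len(s), margin + seq_len(s)] <- sub
      canvas[, , k] <- ch
    }
    canvas <- canvas * gains[i] + stats::rnorm(3 * cs * cs, 0, noise_sd)
    canvas <- round(pmin(pmax(canvas, 0), 255))
    mask <- enhance_mask(threshold_vegetation(rgb_to_hsv(canvas), th), se)
    cm <- filter_small_components(label_components(mask, connectivity), min_area)
    if (nrow(cm$components) == 0) return(canvas)   # degenerate: keep full canvas
    main <- which.max(cm$components$area)
    co <- cm$components[main, ]
    canvas[co$rmin:co$rmax, co$cmin:co$cmax, , drop = FALSE]
  })
  list(patches = patches, labels = classes)
}
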