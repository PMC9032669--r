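# Five-stage orchestration: acquire -> segment -> extract ROIs -> classify ->
# report, with a serializable configuration and deterministic outputs.

#' Pipeline configuration
#'
#' @param thresholds an [hsv_thresholds()] object.
#' @param se_size,se_shape structuring element (default 5x5 box).
#' @param connectivity component connectivity, 4 or 8.
#' @param min_area minimum component area in pixels.
#' @param padding ROI bounding-box padding.
#' @param lbp an [lbp_config()] (used by the SVM route).
#' @param classifier `"svm"` or `"cnn"`.
#' @param seed seed recorded with every run.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = hsv_thresholds(), se_size = 5,
                            se_shape = "box", connectivity = 8, min_area = 400,
                            padding = 0, lbp = lbp_config(),
                            classifier = c("svm", "cnn"), seed = 42) {
  classifier <- match.arg(classifier)
  structure(list(thresholds = thresholds, se_size = se_size,
                 se_shape = se_shape, connectivity = connectivity,
                 min_area = min_area, padding = padding, lbp = lbp,
                 classifier = classifier, seed = seed),
            class = "pipeline_config")
}

#' Read/write a pipeline configuration
#'
#' YAML is the primary format; files ending in `.json` use JSON.
#'
#' @param cfg a `pipeline_config`.
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- list(thresholds = unclass(cfg$thresholds), se_size = cfg$se_size,
            se_shape = cfg$se_shape, connectivity = cfg$connectivity,
            min_area = cfg$min_area, padding = cfg$padding,
            lbp = unclass(cfg$lbp), classifier = cfg$classifier,
            seed = cfg$seed)
  if (grepl("\\.json$", path)) jsonlite::write_json(x, path, auto_unbox = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  pipeline_config(
    thresholds = do.call(hsv_thresholds, x$thresholds),
    se_size = x$se_size, se_shape = x$se_shape,
    connectivity = x$connectivity, min_area = x$min_area,
    padding = x$padding, lbp = do.call(lbp_config, x$lbp),
    classifier = x$classifier, seed = x$seed
  )
}

#' Segment one image into a cleaned mask and component map
#'
#' @param img RGB image array or path to a PNG.
#' @param cfg a [pipeline_config()].
#' @return a list with `mask` (cleaned `{0,255}` matrix) and `components`
#'   (filtered `component_map`).
#' @export
segment_image <- function(img, cfg = pipeline_config()) {
  if (is.character(img)) img <- read_image_png(img)
  se <- structuring_element(cfg$se_size, cfg$se_shape)
  mask <- enhance_mask(threshold_vegetation(rgb_to_hsv(img), cfg$thresholds), se)
  cm <- filter_small_components(label_components(mask, cfg$connectivity),
                                cfg$min_area)
  list(mask = mask, components = cm)
}

#' Run the full detection pipeline on one image
#'
#' Segments the image, extracts one ROI per surviving component, classifies
#' each ROI with the supplied model (SVM over LBP features, or the CNN
#' classifier), and returns the detections plus an annotated copy of the
#' image with class-coloured boxes (green Crop, red NLW, blue BLW).
#'
#' @param img RGB image array or path to a PNG.
#' @param cfg a [pipeline_config()].
#' @param model an `svm_multiclass` (with an LBP fingerprint) or a
#'   `trained_classifier`.
#' @return a list with `detections` (data frame: roi, class, score, rmin,
#'   cmin, rmax, cmax), `annotated` (RGB array), `mask`, `components`.
#' @export
run_pipeline <- function(img, cfg, model) {
  if (is.character(img)) img <- read_image_png(img)
  validate_rgb(img)
  seg <- segment_image(img, cfg)
  patches <- extract_patches(img, seg$components, cfg$padding)
  det <- data.frame(roi = integer(0), class = character(0), score = numeric(0),
                    rmin = integer(0), cmin = integer(0),
                    rmax = integer(0), cmax = integer(0))
  if (length(patches) > 0) {
    if (inherits(model, "svm_multiclass")) {
      if (cfg$classifier != "svm")
        stop("config expects a ", cfg$classifier, " model")
      fp <- lbp_fingerprint(cfg$lbp)
      if (!is.null(model$fingerprint) && !identical(model$fingerprint, fp))
        stop("feature/model mismatch: model was trained with ",
             model$fingerprint, " but the config specifies ", fp)
      feats <- t(vapply(patches, featurize_patch, cfg = cfg$lbp,
                        FUN.VALUE = numeric(feature_length(cfg$lbp))))
      labels <- predict(model, feats)
      scores <- decision_scores(model, feats)
      score <- scores[cbind(seq_len(nrow(scores)), match(labels, colnames(scores)))]
    } else if (inherits(model, "trained_classifier")) {
      if (cfg$classifier != "cnn")
        stop("config expects a ", cfg$classifier, " model")
      pr <- predict_cnn(model, patches)
      labels <- pr$labels
      score <- pr$probs[cbind(seq_len(nrow(pr$probs)),
                              match(labels, colnames(pr$probs)))]
    } else stop("unsupported model object")
    bb <- t(vapply(patches, function(p) p$bbox, numeric(4)))
    det <- data.frame(roi = seq_along(patches), class = labels, score = score,
                      rmin = bb[, 1], cmin = bb[, 2], rmax = bb[, 3],
                      cmax = bb[, 4])
  }
  list(detections = det, annotated = annotate_detections(img, det),
       mask = seg$mask, components = seg$components)
}

#' Draw class-coloured detection boxes on an image
#'
#' Green for Crop, red for NLW, blue for BLW; 3-pixel borders.
#'
#' @param img RGB image array.
#' @param detections detection data frame from [run_pipeline()].
#' @return annotated RGB array.
#' @export
annotate_detections <- function(img, detections) {
  cols <- list(Crop = c(0, 255, 0), NLW = c(255, 0, 0), BLW = c(0, 0, 255))
  m <- dim(img)[1]; n <- dim(img)[2]
  for (i in seq_len(nrow(detections))) {
    d <- detections[i, ]
    col <- cols[[d$class]]
    r1 <- max(1, d$rmin); r2 <- min(m, d$rmax)
    c1 <- max(1, d$cmin); c2 <- min(n, d$cmax)
    for (k in 1:3) {
      band <- 0:2
      img[pmin(pmax(r1 + band, 1), m), c1:c2, k] <- col[k]
      img[pmin(pmax(r2 - band, 1), m), c1:c2, k] <- col[k]
      img[r1:r2, pmin(pmax(c1 + band, 1), n), k] <- col[k]
      img[r1:r2, pmin(pmax(c2 - band, 1), n), k] <- col[k]
    }
  }
  img
}

#' Save or load a trained model
#'
#' Models embed the LBP feature fingerprint (SVM route) so a model cannot be
#' silently applied to features of a different configuration. Files are
#' standard R serializations.
#'
#' @param model an `svm_multiclass` or `trained_classifier`.
#' @param path file path.
#' @return `load_model()` returns the model; `save_model()` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Write detections to CSV or JSON
#'
#' @param detections detection data frame.
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(detections, path, dataframe = "rows")
  else utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}
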