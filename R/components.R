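# Connected-component analysis of the cleaned vegetation mask, small-region
# filtering, and extraction of per-plant RGB patches.

#' Label connected foreground components
#'
#' Every maximal connected region of foreground pixels receives one unique
#' label, 1..K, assigned in raster order (reading rows top-to-bottom, left to
#' right) of each component's first pixel. Adjacency is decided by the
#' `connectivity` argument: 4 (edge neighbours) or 8 (edge + diagonal
#' neighbours, the default, which keeps diagonally touching leaf fragments
#' together).
#'
#' @param mask `{0, 255}` mask matrix.
#' @param connectivity 4 or 8.
#' @return an object of class `component_map`: a list with `labels` (integer
#'   matrix, 0 = background) and `components` (data frame with columns
#'   `label`, `area`, `rmin`, `cmin`, `rmax`, `cmax`).
#' @export
label_components <- function(mask, connectivity = 8) {
  validate_mask(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  m <- nrow(mask); n <- ncol(mask)
  fg <- which(mask > 0)                      # column-major linear indices
  labels <- matrix(0L, m, n)
  if (length(fg) == 0L)
    return(new_component_map(labels, integer(0)))

  vid <- integer(m * n)                      # pixel index -> vertex id
  vid[fg] <- seq_along(fg)
  rows <- ((fg - 1L) %% m) + 1L
  cols <- ((fg - 1L) %/% m) + 1L

  offsets <- list(c(1L, 0L), c(0L, 1L))      # down, right
  if (connectivity == 8)
    offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))  # down-right, up-right
  edges <- lapply(offsets, function(off) {
    rr <- rows + off[1]; cc <- cols + off[2]
    ok <- rr >= 1L & rr <= m & cc >= 1L & cc <= n
    nb <- (cc[ok] - 1L) * m + rr[ok]
    ok2 <- vid[nb] > 0L
    cbind(vid[fg[ok][ok2]], vid[nb[ok2]])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership

  # relabel so that labels follow raster order of each component's first pixel
  raster_pos <- (rows - 1L) * n + cols
  first_pos <- tapply(raster_pos, memb, min)
  new_of_old <- integer(length(first_pos))
  new_of_old[order(first_pos)] <- seq_along(first_pos)
  lab <- new_of_old[memb]
  labels[fg] <- lab
  new_component_map(labels, lab)
}

new_component_map <- function(labels, lab_of_fg) {
  if (length(lab_of_fg) == 0L) {
    comps <- data.frame(label = integer(0), area = integer(0),
                        rmin = integer(0), cmin = integer(0),
                        rmax = integer(0), cmax = integer(0))
    return(structure(list(labels = labels, components = comps),
                     class = "component_map"))
  }
  m <- nrow(labels)
  fg <- which(labels > 0L)
  lab <- labels[fg]
  rows <- ((fg - 1L) %% m) + 1L
  cols <- ((fg - 1L) %/% m) + 1L
  comps <- data.frame(
    label = sort(unique(lab)),
    area  = as.integer(tabulate(lab)),
    rmin  = as.integer(tapply(rows, lab, min)),
    cmin  = as.integer(tapply(cols, lab, min)),
    rmax  = as.integer(tapply(rows, lab, max)),
    cmax  = as.integer(tapply(cols, lab, max))
  )
  rownames(comps) <- NULL
  structure(list(labels = labels, components = comps), class = "component_map")
}

#' @export
print.component_map <- function(x, ...) {
  cat("component_map:", nrow(x$components), "component(s) over a",
      paste(dim(x$labels), collapse = " x "), "mask\n")
  if (nrow(x$components) > 0) print(utils::head(x$components, 10))
  invisible(x)
}

#' Drop components smaller than a minimum area
#'
#' Components whose pixel count is below `min_area` are removed from both the
#' label image and the component table; surviving labels are re-indexed
#' consecutively (1..K') preserving their order.
#'
#' @param cm a `component_map`.
#' @param min_area minimum pixel count to keep (default 400). Components with
#'   `area < min_area` are discarded.
#' @param min_fraction optional alternative: minimum area as a fraction of the
#'   image area; when given, overrides `min_area`.
#' @return a filtered `component_map`.
#' @export
filter_small_components <- function(cm, min_area = 400, min_fraction = NULL) {
  stopifnot(inherits(cm, "component_map"))
  if (!is.null(min_fraction))
    min_area <- min_fraction * length(cm$labels)
  if (min_area < 0) stop("min_area must be non-negative")
  keep <- cm$components$label[cm$components$area >= min_area]
  remap <- integer(max(cm$components$label, 0L) + 1L)   # old label + 1 -> new
  remap[keep + 1L] <- seq_along(keep)
  labels <- matrix(remap[cm$labels + 1L], nrow(cm$labels), ncol(cm$labels))
  new_component_map(labels, labels[labels > 0L])
}

#' Extract per-component RGB patches
#'
#' Crops one patch per component from the original RGB image at the
#' component's bounding box, expanded by `padding` pixels on every side and
#' clipped to the image bounds. Patches are returned in label order.
#'
#' @param rgb the source RGB image the mask was derived from.
#' @param cm a `component_map` with the same spatial dimensions.
#' @param padding non-negative bounding-box expansion in pixels (default 0).
#' @return a list of `roi_patch` objects, each with `pixels` (RGB array),
#'   `bbox` (`c(rmin, cmin, rmax, cmax)` after padding/clipping), `label`,
#'   and `class` (`NA` until annotated).
#' @export
extract_patches <- function(rgb, cm, padding = 0) {
  validate_rgb(rgb)
  stopifnot(inherits(cm, "component_map"))
  if (!all(dim(rgb)[1:2] == dim(cm$labels)))
    stop("component map dimensions do not match the RGB image")
  if (padding < 0) stop("padding must be non-negative")
  m <- dim(rgb)[1]; n <- dim(rgb)[2]
  lapply(seq_len(nrow(cm$components)), function(i) {
    co <- cm$components[i, ]
    r1 <- max(1L, co$rmin - padding); r2 <- min(m, co$rmax + padding)
    c1 <- max(1L, co$cmin - padding); c2 <- min(n, co$cmax + padding)
    structure(list(pixels = rgb[r1:r2, c1:c2, , drop = FALSE],
                   bbox = c(rmin = r1, cmin = c1, rmax = r2, cmax = c2),
                   label = co$label, class = NA_character_),
              class = "roi_patch")
  })
}

#' Write a component table to CSV
#'
#' Columns: `label`, `area`, `bbox_rmin`, `bbox_cmin`, `bbox_rmax`, `bbox_cmax`.
#'
#' @param cm a `component_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_components_csv <- function(cm, path) {
  stopifnot(inherits(cm, "component_map"))
  df <- cm$components
  names(df) <- c("label", "area", "bbox_rmin", "bbox_cmin", "bbox_rmax", "bbox_cmax")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
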