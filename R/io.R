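#' Read an 8-bit RGB image
#'
#' Reads PNG or TIFF into an h x w x 3 integer array on the 0-255 scale.
#' Greyscale inputs and bit depths other than 8 are rejected.
#'
#' @param path image file (.png, .tif, .tiff).
#' @return h x w x 3 array of integers 0..255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) < 3L)
      stop("greyscale image: an RGB image is required (", path, ")")
    img <- round(img[, , 1:3, drop = FALSE] * 255)
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bps <- attr(img, "bits.per.sample")
    if (!is.null(bps) && any(bps != 8L))
      stop("unsupported bit depth (", bps[1], " bits per channel, need 8): ", path)
    if (length(dim(img)) < 3L)
      stop("greyscale image: an RGB image is required (", path, ")")
    img <- round(img[, , 1:3, drop = FALSE] * 255)
  } else stop("unsupported format '", ext, "': use PNG or TIFF")
  storage.mode(img) <- "integer"
  img
}

#' Write an image to PNG or TIFF
#'
#' RGB arrays (h x w x 3) and single-channel matrices are written as 8-bit;
#' integer label masks as 16-bit TIFF.
#'
#' @param img array/matrix of intensities 0..255, or labels for
#'   `write_label_mask`.
#' @param path output file; extension selects the format.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  x <- pmin(pmax(img, 0), 255) / 255
  if (ext == "png") png::writePNG(x, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(x, path, bits.per.sample = 8L)
  else stop("unsupported format: ", ext)
  invisible(path)
}

#' @rdname write_image
#' @export
write_label_mask <- function(img, path) {
  if (max(img) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image
#' @export
read_label_mask <- function(path) {
  m <- round(tiff::readTIFF(path) * 65535)
  storage.mode(m) <- "integer"
  m
}

#' Rasterize polygon region annotations to a label mask
#'
#' Even-odd (crossing number) polygon fill. Coordinates are 0-based `(x, y)`
#' = (column, row) pairs; a pixel belongs to a region when its center
#' `(col + 0.5, row + 0.5)` lies inside the polygon, so an axis-aligned
#' rectangle with corners (0,0) and (10,10) covers exactly the 10 x 10 pixel
#' block (half-open convention, x in `[x0, x1)`). A pixel claimed by several
#' polygons goes to the first.
#'
#' @param polygons list of n x 2 matrices (columns x, y), one per region,
#'   each with at least 3 vertices. Out-of-bounds vertices are allowed; the
#'   filled area is clipped to the image with a warning.
#' @param dim image dimensions `c(height, width)`.
#' @return integer label matrix (region i = label i).
#' @export
rasterize_regions <- function(polygons, dim) {
  h <- dim[1]; w <- dim[2]
  mask <- matrix(0L, h, w)
  for (i in seq_along(polygons)) {
    poly <- as.matrix(polygons[[i]])
    if (nrow(poly) < 3L)
      stop("polygon ", i, " is degenerate: at least 3 vertices required")
    if (any(poly[, 1] < 0 | poly[, 1] > w | poly[, 2] < 0 | poly[, 2] > h))
      warning("polygon ", i, " extends outside the image; clipping")
    xs <- max(0L, floor(min(poly[, 1]))):min(w - 1L, ceiling(max(poly[, 1])))
    ys <- max(0L, floor(min(poly[, 2]))):min(h - 1L, ceiling(max(poly[, 2])))
    if (length(xs) == 0L || length(ys) == 0L) next
    px <- rep(xs, times = length(ys)) + 0.5
    py <- rep(ys, each = length(xs)) + 0.5
    inside <- point_in_polygon(px, py, poly)
    rows <- rep(ys, each = length(xs))[inside] + 1L
    cols <- rep(xs, times = length(ys))[inside] + 1L
    sel <- mask[cbind(rows, cols)] == 0L
    mask[cbind(rows[sel], cols[sel])] <- i
  }
  mask
}

# even-odd rule by ray casting, vectorized over query points
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read region annotations from a GeoJSON-like file
#'
#' Accepts a JSON FeatureCollection of Polygon features (first ring used),
#' or a plain JSON list of coordinate arrays. Coordinates are 0-based
#' (x, y) pixel positions.
#'
#' @param path JSON file.
#' @return list of n x 2 coordinate matrices.
#' @export
read_regions <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (!is.null(j$features)) lapply(j$features, function(f)
    f$geometry$coordinates[[1]]) else j
  lapply(feats, function(ring)
    do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))[1:2])))
}

#' Write region measurements to CSV
#'
#' Stable column order `region, n_cells, n_negative, n_weak, n_moderate,
#' n_strong, frac_weak, frac_moderate, frac_strong, pct_positive,
#' mean_intensity, score`; floats rounded to 4 decimals; rows ordered by
#' region id.
#'
#' @param measurements data.frame from [score_regions()].
#' @param path output CSV.
#' @export
write_measurements <- function(measurements, path) {
  cols <- c("region", "n_cells", "n_negative", "n_weak", "n_moderate",
            "n_strong", "frac_weak", "frac_moderate", "frac_strong",
            "pct_positive", "mean_intensity", "score")
  d <- measurements[, cols, drop = FALSE]
  d <- d[order(d$region), , drop = FALSE]
  num <- vapply(d, is.double, logical(1))
  d[num] <- lapply(d[num], function(z) round(z, 4))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a decalcification time-course table
#'
#' CSV with header `case,marker,time_h,field,value`.
#'
#' @param table data.frame to write.
#' @param path CSV file.
#' @export
write_timecourse <- function(table, path) {
  utils::write.csv(table[, c("case", "marker", "time_h", "field", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("case", "marker", "time_h", "field", "value")
  if (!all(req %in% names(d)))
    stop("time-course CSV must have header ", paste(req, collapse = ","))
  d
}

#' Load and validate a run configuration
#'
#' YAML or JSON; unknown keys are rejected, missing keys filled with the
#' package defaults. The fully resolved configuration is what every command
#' echoes into its outputs for provenance.
#'
#' @param path config file, or NULL for pure defaults.
#' @return named list of settings.
#' @export
load_config <- function(path = NULL) {
  defaults <- list(
    stain_vectors = list(hematoxylin = c(0.650, 0.704, 0.286),
                         dab = c(0.268, 0.570, 0.776)),
    t0 = "auto", k = 3L, em_tol = 1e-6, em_max_iter = 500L,
    weighted_intersections = TRUE,
    fraction_denominator = "positive", intensity_mode = "positive",
    min_area = 20L)
  if (is.null(path)) return(defaults)
  cfg <- if (tolower(tools::file_ext(path)) %in% c("yml", "yaml"))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, cfg)
}

config_stain_vectors <- function(cfg) {
  sv <- cfg$stain_vectors
  stain_vectors(sv$hematoxylin, sv$dab, sv$residual)
}
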