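#' Normalized per-channel histograms of a rectangular region
#'
#' Extracts 256-bin normalized histograms of the red, green and blue
#' channels, plus a monochrome channel, from a rectangle of an RGB image --
#' the basis of the between-instrument image-capture comparison.
#'
#' @param img h x w x 3 RGB array (0-255).
#' @param rect rectangle `c(x0, y0, x1, y1)` in 0-based pixel coordinates,
#'   half-open (`x in [x0, x1)`), or NULL for the whole image.
#' @param mono "mean" (default; rounded unweighted RGB mean) or "luminance"
#'   (Rec. 601 weights 0.299/0.587/0.114).
#' @return object of class `channel_histograms`: list of four normalized
#'   256-bin vectors (`r`, `g`, `b`, `mono`, grey levels 0..255) plus the
#'   region descriptor.
#' @export
channel_histograms <- function(img, rect = NULL, mono = c("mean", "luminance")) {
  mono <- match.arg(mono)
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stop("img must be h x w x 3")
  if (is.null(rect)) rect <- c(0L, 0L, d[2], d[1])
  x0 <- rect[1]; y0 <- rect[2]; x1 <- rect[3]; y1 <- rect[4]
  if (x0 < 0 || y0 < 0 || x1 > d[2] || y1 > d[1] || x1 <= x0 || y1 <= y0)
    stop("rectangle empty or out of image bounds")
  sub <- img[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  wgt <- if (mono == "mean") c(1, 1, 1) / 3 else c(0.299, 0.587, 0.114)
  mc <- round(sub[, , 1] * wgt[1] + sub[, , 2] * wgt[2] + sub[, , 3] * wgt[3])
  norm_hist <- function(v) {
    h <- tabulate(pmin(pmax(round(v), 0), 255) + 1L, nbins = 256L)
    h / sum(h)
  }
  structure(list(r = norm_hist(sub[, , 1]), g = norm_hist(sub[, , 2]),
                 b = norm_hist(sub[, , 3]), mono = norm_hist(mc),
                 rect = c(x0 = x0, y0 = y0, x1 = x1, y1 = y1), mono_mode = mono),
            class = "channel_histograms")
}

#' Histogram mass per staining-intensity zone
#'
#' Splits each channel histogram into the four intensity zones defined by
#' the category thresholds -- strong `[0, t1]`, moderate `(t1, t2]`, weak
#' `(t2, t0]`, negative+background `(t0, 255]` -- and returns the mass in
#' each (the areas under the normalized histogram).
#'
#' @param hist a [channel_histograms()] object.
#' @param thresholds a [category_thresholds()].
#' @return matrix: rows = channels (r, g, b, mono), columns = zones
#'   (strong, moderate, weak, negative_background); rows sum to 1.
#' @export
zone_areas <- function(hist, thresholds) {
  stopifnot(inherits(hist, "channel_histograms"),
            inherits(thresholds, "category_thresholds"))
  lev <- 0:255
  zone <- ifelse(lev <= thresholds$t1, "strong",
          ifelse(lev <= thresholds$t2, "moderate",
          ifelse(lev <= thresholds$t0, "weak", "negative_background")))
  zones <- c("strong", "moderate", "weak", "negative_background")
  out <- t(vapply(hist[c("r", "g", "b", "mono")], function(h)
    vapply(zones, function(z) sum(h[zone == z]), numeric(1)),
    numeric(4)))
  colnames(out) <- zones
  out
}

#' Pixelwise intensity correspondence between two aligned images
#'
#' Pearson correlation over all pixel pairs of two pre-aligned monochrome
#' images, plus the mean mapping curve: for each grey level v occurring in
#' image A, the mean intensity of the co-located pixels in image B.
#'
#' @param a,b monochrome matrices of identical dimensions (0-255).
#' @return list with `r` (Pearson correlation; NA with `constant = TRUE`
#'   when either image is constant), `curve` (data.frame intensity, mean_b,
#'   n; levels absent from A have n = 0 and NA mean).
#' @export
intensity_correspondence <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("images must have identical dimensions")
  av <- as.numeric(a); bv <- as.numeric(b)
  constant <- stats::sd(av) == 0 || stats::sd(bv) == 0
  r <- if (constant) NA_real_ else stats::cor(av, bv)
  lev <- pmin(pmax(round(av), 0), 255)
  n <- tabulate(lev + 1L, nbins = 256L)
  s <- rowsum(bv, lev)
  mean_b <- rep(NA_real_, 256L)
  mean_b[as.integer(rownames(s)) + 1L] <- s[, 1] / n[as.integer(rownames(s)) + 1L]
  list(r = r, constant = constant,
       curve = data.frame(intensity = 0:255, mean_b = mean_b, n = n))
}

#' Monochrome version of an RGB image
#' @inheritParams channel_histograms
#' @export
to_monochrome <- function(img, mono = c("mean", "luminance")) {
  mono <- match.arg(mono)
  wgt <- if (mono == "mean") c(1, 1, 1) / 3 else c(0.299, 0.587, 0.114)
  round(img[, , 1] * wgt[1] + img[, , 2] * wgt[2] + img[, , 3] * wgt[3])
}
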