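#' Segment nuclei from a hematoxylin white-intensity image
#'
#' Otsu threshold on the hematoxylin white-intensity histogram; foreground =
#' pixels at or below the threshold (darker = more stain); 8-connected
#' components; components smaller than `min_area` are dropped and labels
#' renumbered 1..N.
#'
#' @param hematoxylin h x w matrix of white intensities (0-255).
#' @param min_area minimum component area in pixels (default 20).
#' @return integer label matrix, 0 = background.
#' @export
segment_nuclei <- function(hematoxylin, min_area = 20L) {
  hist <- tabulate(pmin(pmax(round(hematoxylin), 0), 255) + 1L, nbins = 256L)
  thr <- global_threshold(hist)
  if (isTRUE(attr(thr, "degenerate")))   # constant image: nothing to segment
    return(matrix(0L, nrow(hematoxylin), ncol(hematoxylin)))
  fg <- hematoxylin <= thr
  lab <- label_components(fg)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(sizes >= min_area)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so labels
# touching only diagonally are merged through an adjacency graph
label_components <- function(fg) {
  lab <- EBImage::bwlabel(matrix(as.numeric(fg), nrow(fg), ncol(fg)))
  lab <- matrix(as.integer(lab), nrow(fg), ncol(fg))
  nmax <- max(lab)
  if (nmax <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1])))  # up-right
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) > 0L) {
    g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nmax - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    lab[lab > 0L] <- comp[lab[lab > 0L]]
  }
  # renumber to consecutive labels
  u <- sort(unique(lab[lab > 0L]))
  remap <- integer(max(u))
  remap[u] <- seq_along(u)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Per-nucleus DAB positivity
#'
#' For each labelled nucleus computes the mean DAB white intensity and flags
#' it positive when the mean is at or below the background cutoff t0 (a mean
#' above t0 means no detectable DAB: negative).
#'
#' @param dab h x w DAB white-intensity matrix.
#' @param mask integer label matrix from [segment_nuclei()] (or ground truth).
#' @param t0 background cutoff.
#' @return data.frame with `label`, `area`, `mean_intensity`, `positive`.
#' @export
nucleus_positivity <- function(dab, mask, t0) {
  labs <- mask[mask > 0L]
  if (length(labs) == 0L)
    return(data.frame(label = integer(0), area = integer(0),
                      mean_intensity = numeric(0), positive = logical(0)))
  vals <- dab[mask > 0L]
  area <- tabulate(labs, nbins = max(labs))
  s <- rowsum(vals, labs)
  present <- which(area > 0L)
  data.frame(label = present, area = area[present],
             mean_intensity = as.numeric(s[as.character(present), 1]) / area[present],
             positive = as.numeric(s[as.character(present), 1]) / area[present] <= t0)
}

#' Percent positive per field, with mean and SD across fields
#'
#' @param positive logical vector of per-nucleus positivity flags.
#' @param field grouping vector (field id per nucleus); a single field by
#'   default.
#' @return list with `per_field` (data.frame field, n, percent), `mean`, `sd`
#'   (SD is NA with a single field).
#' @export
percent_positive <- function(positive, field = rep(1L, length(positive))) {
  if (length(positive) == 0L) stop("empty group: no nuclei to summarize")
  per <- stats::aggregate(positive, by = list(field = field),
                          FUN = function(z) 100 * mean(z))
  n <- stats::aggregate(positive, by = list(field = field), FUN = length)
  pf <- data.frame(field = per$field, n = n$x, percent = per$x)
  list(per_field = pf, mean = mean(pf$percent),
       sd = if (nrow(pf) > 1L) stats::sd(pf$percent) else NA_real_)
}

#' Mean DAB white intensity of a delineated region
#'
#' @param dab DAB white-intensity matrix.
#' @param region logical or 0/1 matrix delineating the region.
#' @param t0 background cutoff.
#' @param mode "positive" (default) averages only pixels at or below t0;
#'   "all" averages every region pixel.
#' @return list with `mean` (NA if no positive pixel in positive mode),
#'   `n_pixels`, `mode`, `no_positive` flag.
#' @export
region_mean_intensity <- function(dab, region, t0, mode = c("positive", "all")) {
  mode <- match.arg(mode)
  v <- dab[region > 0]
  if (length(v) == 0L) stop("empty region")
  if (mode == "positive") v <- v[v <= t0]
  no_pos <- length(v) == 0L
  list(mean = if (no_pos) NA_real_ else mean(v),
       n_pixels = length(v), mode = mode, no_positive = no_pos)
}

#' Fraction-weighted categorical score
#'
#' score = 1 * f_weak + 2 * f_moderate + 3 * f_strong, the category fractions
#' multiplied by their ranks, yielding a continuous score on 0-3 (3 when all
#' positive cells stain strongly).
#'
#' @param fractions numeric(3): fractions of weak, moderate and strong cells
#'   (each >= 0, summing to at most 1; any remainder is the negative
#'   fraction when the all-cells denominator is used).
#' @return numeric score in `[0, 3]`.
#' @examples
#' weighted_score(c(0, 0, 1))      # 3
#' weighted_score(c(1, 1, 1) / 3)  # 2
#' @export
weighted_score <- function(fractions) {
  f <- as.numeric(fractions)
  if (length(f) != 3L) stop("fractions must be (weak, moderate, strong)")
  if (any(f < 0)) stop("fractions must be non-negative")
  if (sum(f) > 1 + 1e-9) stop("fractions must sum to at most 1")
  sum(c(1, 2, 3) * f)
}

#' Score regions of an H-DAB image
#'
#' End-to-end measurement: segment nuclei on the hematoxylin channel (or use
#' a supplied nucleus mask), take each cell's mean DAB white intensity,
#' categorize it against the thresholds, and summarize each region with
#' category counts, fractions, percent positive, mean intensity and the
#' weighted 0-3 score. A cell belongs to the region containing its centroid
#' pixel; with `regions = NULL` the whole image is one region.
#'
#' @param channels list with `hematoxylin` and `dab` white-intensity
#'   matrices, e.g. from [separate_stains()].
#' @param thresholds a [category_thresholds()].
#' @param regions optional integer region-label matrix (0 = unassigned).
#' @param nucleus_mask optional precomputed nucleus label matrix.
#' @param min_area passed to [segment_nuclei()].
#' @param denominator fraction denominator, see [categorize_intensities()].
#' @param intensity_mode region mean mode, see [region_mean_intensity()].
#' @return data.frame, one row per region, with columns `region`, `n_cells`,
#'   `n_negative`, `n_weak`, `n_moderate`, `n_strong`, `frac_weak`,
#'   `frac_moderate`, `frac_strong`, `pct_positive`, `mean_intensity`,
#'   `score`.
#' @export
score_regions <- function(channels, thresholds, regions = NULL,
                          nucleus_mask = NULL, min_area = 20L,
                          denominator = c("positive", "all"),
                          intensity_mode = c("positive", "all")) {
  denominator <- match.arg(denominator)
  intensity_mode <- match.arg(intensity_mode)
  dab <- channels$dab
  if (is.null(nucleus_mask))
    nucleus_mask <- segment_nuclei(channels$hematoxylin, min_area = min_area)
  if (is.null(regions)) regions <- matrix(1L, nrow(dab), ncol(dab))
  rec <- nucleus_positivity(dab, nucleus_mask, thresholds$t0)
  if (nrow(rec) > 0L) {
    cent <- cell_centroids(nucleus_mask, rec$label)
    rec$region <- regions[cbind(pmin(pmax(round(cent$row), 1), nrow(regions)),
                                pmin(pmax(round(cent$col), 1), ncol(regions)))]
  } else rec$region <- integer(0)
  region_ids <- sort(unique(regions[regions > 0L]))
  out <- lapply(region_ids, function(rid) {
    rr <- rec[rec$region == rid, , drop = FALSE]
    cats <- categorize_intensities(rr$mean_intensity, thresholds,
                                   denominator = denominator)
    cnt <- as.numeric(cats$counts)
    mi <- region_mean_intensity(dab, regions == rid, thresholds$t0,
                                mode = intensity_mode)
    data.frame(region = rid, n_cells = nrow(rr),
               n_negative = cnt[1], n_weak = cnt[2], n_moderate = cnt[3],
               n_strong = cnt[4],
               frac_weak = cats$fractions["weak"],
               frac_moderate = cats$fractions["moderate"],
               frac_strong = cats$fractions["strong"],
               pct_positive = if (nrow(rr) > 0L) 100 * mean(rr$positive) else NA_real_,
               mean_intensity = mi$mean,
               score = weighted_score(cats$fractions),
               row.names = NULL)
  })
  do.call(rbind, out)
}

cell_centroids <- function(mask, labels) {
  idx <- which(mask > 0L, arr.ind = TRUE)
  labs <- mask[mask > 0L]
  r <- rowsum(cbind(idx[, 1], idx[, 2], 1), labs)
  data.frame(label = as.integer(rownames(r)),
             row = r[, 1] / r[, 3], col = r[, 2] / r[, 3])[
               match(labels, as.integer(rownames(r))), ]
}

#' Normalize a time-course table to its time-zero baseline
#'
#' Per case and marker, field values are expressed as a percentage of that
#' case's mean at time zero, so the time-zero group mean maps to 100 exactly.
#'
#' @param table data.frame with columns case, marker, time_h, field, value.
#' @return the table with `value` replaced by `value_pct`.
#' @export
normalize_to_baseline <- function(table) {
  req <- c("case", "marker", "time_h", "field", "value")
  if (!all(req %in% names(table))) stop("time-course table must have columns ",
                                        paste(req, collapse = ", "))
  key <- interaction(table$case, table$marker, drop = TRUE)
  out <- lapply(split(table, key), function(d) {
    base <- d$value[d$time_h == 0]
    if (length(base) == 0L || mean(base) == 0)
      stop("missing or zero time-zero baseline for case ", d$case[1],
           " marker ", d$marker[1])
    d$value_pct <- 100 * d$value / mean(base)
    d$value <- NULL
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$case, res$marker, res$time_h, res$field), ]
}

#' Coefficient of variation across fields, in percent
#'
#' 100 * sample SD / mean -- the intra-tumor heterogeneity measure across
#' the measured fields of one slide.
#'
#' @param values numeric field values (>= 2 of them).
#' @return percent CV; NA with attribute `undefined = TRUE` when the mean
#'   is zero.
#' @export
percent_cv <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values for a CV")
  m <- mean(values)
  if (m == 0) return(structure(NA_real_, undefined = TRUE))
  100 * stats::sd(values) / m
}
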