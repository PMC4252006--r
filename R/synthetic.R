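#' Specification of a synthetic H-DAB image
#'
#' Parameters of the ground-truthed synthetic tissue-field generator. Nuclei
#' are non-overlapping ellipses; DAB-negative cells carry hematoxylin only,
#' positive cells additionally carry a DAB amount whose reconstructed white
#' intensity equals the cell's assigned value (before pixel noise).
#'
#' Defaults emulate a calibration field: DAB white intensities of positive
#' cells follow the 3-component mixture pi = (0.3, 0.4, 0.3),
#' mu = (40, 130, 205), sd = (15, 25, 12) truncated to `[1, t0]` with
#' t0 = 230, and 35 percent of cells are DAB-positive.
#'
#' @param width,height image size in pixels.
#' @param n_cells number of nuclei to place.
#' @param radius_range min/max semi-axis of the elliptical nuclei (pixels).
#' @param dab_model [mixture_model()] for positive-cell DAB white intensity.
#' @param negative_fraction fraction of DAB-negative cells.
#' @param hematoxylin_mean,hematoxylin_sd per-cell hematoxylin white
#'   intensity distribution.
#' @param background background white level (default 255).
#' @param noise_sd additive i.i.d. Gaussian pixel noise in RGB space.
#' @param t0 background cutoff used for the ground-truth categories and the
#'   truncation of positive intensities.
#' @param vectors [stain_vectors()] used by the Beer-Lambert forward model
#'   (the same vectors invert it in [separate_stains()]).
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @export
synthetic_image_spec <- function(width = 450L, height = 450L, n_cells = 250L,
                                 radius_range = c(4, 8),
                                 dab_model = mixture_model(c(0.3, 0.4, 0.3),
                                                          c(40, 130, 205),
                                                          c(15, 25, 12)),
                                 negative_fraction = 0.65,
                                 hematoxylin_mean = 160, hematoxylin_sd = 10,
                                 background = 255, noise_sd = 0,
                                 t0 = 230, vectors = hdab_stain_vectors(),
                                 seed = 1L) {
  stopifnot(n_cells >= 0, width > 0, height > 0,
            length(radius_range) == 2L, radius_range[1] > 0,
            radius_range[2] >= radius_range[1],
            negative_fraction >= 0, negative_fraction <= 1,
            noise_sd >= 0, background > 0, background <= 255)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_cells = as.integer(n_cells), radius_range = radius_range,
                 dab_model = dab_model, negative_fraction = negative_fraction,
                 hematoxylin_mean = hematoxylin_mean,
                 hematoxylin_sd = hematoxylin_sd,
                 background = background, noise_sd = noise_sd,
                 t0 = t0, vectors = vectors, seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

#' Sample white intensities from a Gaussian mixture
#'
#' Draws each value by picking a component according to the mixing weights
#' and then sampling that component's Gaussian; values are clipped to
#' `[0, 255]`. Reproducible given the seed.
#'
#' @param model a [mixture_model()].
#' @param n sample size.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @export
generate_mixture_sample <- function(model, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(model$k, n, replace = TRUE, prob = model$weights)
  x <- stats::rnorm(n, model$means[comp], model$sds[comp])
  pmin(pmax(x, 0), 255)
}

# mixture draw truncated to [lo, hi] by per-value rejection
sample_mixture_truncated <- function(model, n, lo, hi, max_rounds = 1000L) {
  out <- numeric(0)
  for (i in seq_len(max_rounds)) {
    need <- n - length(out)
    if (need <= 0L) break
    comp <- sample.int(model$k, need, replace = TRUE, prob = model$weights)
    x <- stats::rnorm(need, model$means[comp], model$sds[comp])
    out <- c(out, x[x >= lo & x <= hi])
  }
  if (length(out) < n)
    stop("truncated mixture sampling failed: mixture has almost no mass in range")
  out[seq_len(n)]
}

#' Generate a ground-truthed synthetic H-DAB image
#'
#' Places non-overlapping elliptical nuclei by rejection sampling, assigns
#' each cell a hematoxylin white intensity and (if DAB-positive) a DAB white
#' intensity drawn from the spec's mixture, and composes the RGB image with
#' the Beer-Lambert forward model `OD = M c`, so that color deconvolution
#' with the same stain vectors recovers the assigned intensities (within
#' integer rounding, exactly at zero noise).
#'
#' @param spec a [synthetic_image_spec()].
#' @return list with `image` (h x w x 3 integer RGB array), `mask` (h x w
#'   integer label matrix, 0 = background), `cells` (data.frame of per-cell
#'   ground truth: label, x, y, axes, angle, dab and hematoxylin white
#'   intensity, category), `model` (the generating mixture), `thresholds`
#'   (the analytic [category_thresholds()] of the generating mixture).
#' @examples
#' gt <- generate_ihc_image(synthetic_image_spec(width = 120, height = 120,
#'                                               n_cells = 20, seed = 7))
#' table(gt$cells$category)
#' @export
generate_ihc_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width; n <- spec$n_cells
  rmax <- spec$radius_range[2]

  # analytic thresholds of the generating mixture define ground-truth categories
  ts <- component_intersections(spec$dab_model)
  thresholds <- category_thresholds(t0 = spec$t0, t1 = ts[1], t2 = ts[2])

  # --- placement: rejection sampling of non-overlapping ellipses ----------
  # bounding circles (max semi-axis) must be >= 2 px apart so that nuclei
  # never touch, even diagonally; ground truth stays unambiguous
  cx <- cy <- a <- b <- ang <- numeric(n)
  placed <- 0L
  if (n > 0L) {
    attempts_per_cell <- 300L
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(attempts_per_cell)) {
        x0 <- stats::runif(1, rmax + 1, w - rmax - 1)
        y0 <- stats::runif(1, rmax + 1, h - rmax - 1)
        if (placed > 0L) {
          d2 <- (cx[seq_len(placed)] - x0)^2 + (cy[seq_len(placed)] - y0)^2
          if (min(d2) < (2 * rmax + 2)^2) next
        }
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf("could not place all nuclei: %d of %d placed; reduce n_cells or enlarge the image",
                     placed, n))
      placed <- placed + 1L
      cx[i] <- x0; cy[i] <- y0
      ax <- sort(stats::runif(2, spec$radius_range[1], spec$radius_range[2]))
      a[i] <- ax[2]; b[i] <- ax[1]
      ang[i] <- stats::runif(1, 0, pi)
    }
  }

  # --- per-cell ground-truth intensities ----------------------------------
  n_neg <- round(spec$negative_fraction * n)
  is_neg <- rep(FALSE, n)
  if (n > 0L && n_neg > 0L) is_neg[sample.int(n, n_neg)] <- TRUE
  dab <- rep(NA_real_, n)
  if (any(!is_neg))
    dab[!is_neg] <- round(sample_mixture_truncated(spec$dab_model, sum(!is_neg),
                                                   lo = 1, hi = spec$t0))
  hema <- pmin(pmax(round(stats::rnorm(n, spec$hematoxylin_mean,
                                       spec$hematoxylin_sd)), 40), 254)
  category <- rep("negative", n)
  if (any(!is_neg))
    category[!is_neg] <- as.character(
      categorize_intensities(dab[!is_neg], thresholds)$category)

  # --- rasterize and compose ----------------------------------------------
  mask <- matrix(0L, h, w)
  conc <- array(0, dim = c(h, w, 3))  # hematoxylin, dab, residual
  for (i in seq_len(n)) {
    xr <- max(1L, floor(cx[i] - a[i])):min(w, ceiling(cx[i] + a[i]))
    yr <- max(1L, floor(cy[i] - a[i])):min(h, ceiling(cy[i] + a[i]))
    gx <- rep(xr, each = length(yr)) - cx[i]
    gy <- rep(yr, times = length(xr)) - cy[i]
    u <- gx * cos(ang[i]) + gy * sin(ang[i])
    v <- -gx * sin(ang[i]) + gy * cos(ang[i])
    inside <- (u / a[i])^2 + (v / b[i])^2 <= 1
    rows <- rep(yr, times = length(xr))[inside]
    cols <- rep(xr, each = length(yr))[inside]
    idx <- cbind(rows, cols)
    mask[idx] <- i
    conc[cbind(rows, cols, 1L)] <- -log10(hema[i] / 255)
    if (!is_neg[i]) conc[cbind(rows, cols, 2L)] <- -log10(dab[i] / 255)
  }
  od <- compose_od(conc, spec$vectors)
  img <- od_to_rgb(od, I0 = 255, eps = 0)
  bg <- mask == 0L
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[bg] <- spec$background
    img[, , ch] <- plane
  }
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  img <- round(pmin(pmax(img, 0), 255))

  cells <- data.frame(label = seq_len(n), x = cx, y = cy, a = a, b = b,
                      angle = ang, dab_intensity = dab,
                      hematoxylin_intensity = hema,
                      category = factor(category, levels = c("negative", "weak",
                                                             "moderate", "strong")))
  list(image = img, mask = mask, cells = cells,
       model = spec$dab_model, thresholds = thresholds, spec = spec)
}

#' Generate a synthetic decalcification time course
#'
#' Emulates a decalcification study: each case has a baseline staining level,
#' each time point a multiplicative effect relative to time zero, and each
#' measured field multiplicative Gaussian noise with the given coefficient of
#' variation. value(case, time, field) =
#' baseline_case x effect(time) x (1 + N(0, cv)).
#'
#' Defaults mirror a nuclear-marker study: 9 cases, 5 fields per slide,
#' times 0/1/6/24 h, effects (1, 0.85, 0.80, 0.80) -- a 15 percent loss after
#' one hour that plateaus between 6 and 24 h -- and a 5 percent field CV.
#'
#' @param baseline_mean,baseline_sd mean and between-case SD of the case
#'   baselines (white-intensity or percent units; values are floored at 0).
#' @param effects multiplicative effect per time point; effects[1] must be 1.
#' @param field_cv field-level coefficient of variation (fraction, >= 0).
#' @param n_cases,n_fields study size.
#' @param times decalcification times in hours.
#' @param marker marker name recorded in the table.
#' @param seed integer seed, or NULL.
#' @return data.frame with columns `case`, `marker`, `time_h`, `field`,
#'   `value` (n_cases x length(times) x n_fields rows).
#' @export
generate_timecourse <- function(baseline_mean = 80, baseline_sd = 10,
                                effects = c(1, 0.85, 0.80, 0.80),
                                field_cv = 0.05,
                                n_cases = 9L, n_fields = 5L,
                                times = c(0, 1, 6, 24),
                                marker = "ER", seed = NULL) {
  if (n_cases < 1 || n_fields < 1) stop("n_cases and n_fields must be >= 1")
  if (length(effects) != length(times)) stop("one effect per time point required")
  if (abs(effects[1] - 1) > 1e-12) stop("effects[1] must be 1 (time zero is the reference)")
  if (field_cv < 0) stop("field_cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  baseline <- pmax(stats::rnorm(n_cases, baseline_mean, baseline_sd),
                   baseline_mean / 10)
  grid <- expand.grid(field = seq_len(n_fields), time_h = times,
                      case = seq_len(n_cases))
  eff <- effects[match(grid$time_h, times)]
  noise <- 1 + stats::rnorm(nrow(grid), 0, field_cv)
  value <- pmax(baseline[grid$case] * eff * noise, 0)
  data.frame(case = grid$case, marker = marker, time_h = grid$time_h,
             field = grid$field, value = value)
}
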