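#' Three-component Gaussian mixture model of DAB white intensities
#'
#' Container for the mixture fitted to positive-pixel white intensities.
#' Components are kept sorted by ascending mean: the lowest-mean component is
#' the strongest staining (darkest pixels).
#'
#' @param weights mixing fractions, sum 1.
#' @param means component means on the 0-255 white-intensity scale.
#' @param sds component standard deviations, all > 0.
#' @param loglik,iter optional fit diagnostics.
#' @return object of class `mixture_model`.
#' @export
mixture_model <- function(weights, means, sds, loglik = NA_real_, iter = NA_integer_) {
  k <- length(weights)
  if (length(means) != k || length(sds) != k)
    stop("weights, means and sds must have equal length")
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (any(weights < 0)) stop("mixture weights must be non-negative")
  if (any(sds <= 0)) stop("mixture sds must be positive")
  if (any(means < 0 | means > 255)) stop("mixture means must lie in [0, 255]")
  o <- order(means)
  structure(list(weights = as.numeric(weights[o]), means = as.numeric(means[o]),
                 sds = as.numeric(sds[o]), k = k,
                 loglik = loglik, iter = iter),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("Gaussian mixture, k = %d\n", x$k))
  print(data.frame(weight = round(x$weights, 4), mean = round(x$means, 2),
                   sd = round(x$sds, 2)))
  if (is.finite(x$loglik))
    cat(sprintf("log-likelihood %.3f after %d iterations\n", x$loglik, x$iter))
  invisible(x)
}

#' Mixture density on the white-intensity axis
#' @param model a [mixture_model()].
#' @param x evaluation points.
#' @param component single component index, or NULL for the full mixture.
#' @param weighted scale component densities by their mixing weight.
#' @export
mixture_density <- function(model, x, component = NULL, weighted = TRUE) {
  if (!is.null(component)) {
    w <- if (weighted) model$weights[component] else 1
    return(w * stats::dnorm(x, model$means[component], model$sds[component]))
  }
  rowSums(vapply(seq_len(model$k), function(s)
    model$weights[s] * stats::dnorm(x, model$means[s], model$sds[s]),
    numeric(length(x))))
}

#' Category thresholds on the white-intensity scale
#'
#' t0 is the background cutoff (above it: no stain / negative), t1 the
#' strong/moderate boundary, t2 the moderate/weak boundary; the ordering
#' 0 < t1 < t2 < t0 <= 255 is enforced. The boundary convention everywhere is
#' "value <= threshold belongs to the stronger side", matching interval
#' definitions such as strong 0-85, moderate 86-180, weak 181-230.
#'
#' @param t0,t1,t2 thresholds, 0-255.
#' @export
category_thresholds <- function(t0, t1, t2) {
  if (!(0 < t1 && t1 < t2 && t2 < t0 && t0 <= 255))
    stop(sprintf("invalid thresholds: need 0 < t1 < t2 < t0 <= 255, got t1=%.3g t2=%.3g t0=%.3g",
                 t1, t2, t0))
  structure(list(t0 = t0, t1 = t1, t2 = t2), class = "category_thresholds")
}

#' @export
print.category_thresholds <- function(x, ...) {
  cat(sprintf("thresholds: t1 = %.2f (strong/moderate), t2 = %.2f (moderate/weak), t0 = %.2f (background)\n",
              x$t1, x$t2, x$t0))
  invisible(x)
}

#' Global histogram threshold (Otsu)
#'
#' Returns the integer threshold t maximizing the between-class variance of
#' the split {bins <= t} vs {bins > t}; ties are broken toward the smallest
#' threshold. Used for the background cutoff t0 (on a DAB white-intensity
#' histogram) and for foreground detection in nuclear segmentation. An
#' explicit `override` (e.g. the fixed cutoff 230) bypasses the computation.
#'
#' @param counts integer vector of 256 histogram counts for grey levels
#'   0..255 (shorter vectors are zero-padded).
#' @param override optional fixed threshold returned as-is.
#' @return integer threshold. If the histogram has a single occupied bin the
#'   result is that bin, with attribute `degenerate = TRUE`.
#' @export
global_threshold <- function(counts, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  counts <- as.numeric(counts)
  if (length(counts) > 256L) stop("histogram must have at most 256 bins")
  counts <- c(counts, numeric(256L - length(counts)))
  n <- sum(counts)
  if (n <= 0) stop("empty histogram")
  lev <- 0:255
  occupied <- which(counts > 0) - 1L
  if (length(occupied) == 1L)
    return(structure(occupied, degenerate = TRUE))
  w0 <- cumsum(counts) / n                  # mass of class {<= t}
  m0 <- cumsum(counts * lev) / n            # first moment of class {<= t}
  mt <- m0[256L]
  w1 <- 1 - w0
  # between-class variance at each candidate t = 0..254
  valid <- w0[1:255] > 0 & w1[1:255] > 0
  bcv <- rep(-Inf, 255L)
  bcv[valid] <- (mt * w0[1:255][valid] - m0[1:255][valid])^2 /
    (w0[1:255][valid] * w1[1:255][valid])
  m <- max(bcv)
  # ties (exact plateaus across empty bins) break toward the smallest threshold
  as.integer(which(bcv >= m - abs(m) * 1e-10)[1] - 1L)
}

#' One-dimensional k-means (Lloyd) with quantile initialization
#'
#' Deterministic by default: initial centers are the k evenly spaced
#' quantiles of the data, followed by Lloyd iterations to convergence.
#' Supports frequency weights so it can run directly on a histogram.
#'
#' @param x numeric values.
#' @param k number of clusters.
#' @param weights optional non-negative frequency weights, same length as x.
#' @param max_iter iteration cap.
#' @return list with `centers` (ascending), `cluster` (assignment per value),
#'   `sse` (within-cluster weighted sum of squares) and `iter`.
#' @export
kmeans_1d <- function(x, k, weights = NULL, max_iter = 200L) {
  x <- as.numeric(x)
  if (is.null(weights)) weights <- rep(1, length(x))
  keep <- weights > 0
  ux <- unique(x[keep])
  if (length(ux) < k) stop("need at least k distinct values for k-means")
  centers <- sort(unique(weighted_quantile(x, weights, probs = (seq_len(k) - 0.5) / k)))
  # quantile collisions: fall back to evenly spread distinct values
  if (length(centers) < k)
    centers <- sort(ux)[round(seq(1, length(ux), length.out = k))]
  cluster <- rep(0L, length(x))
  for (it in seq_len(max_iter)) {
    d <- outer(x, centers, function(a, b) (a - b)^2)
    new_cluster <- max.col(-d, ties.method = "first")
    if (identical(new_cluster, cluster)) break
    cluster <- new_cluster
    for (j in seq_len(k)) {
      sel <- cluster == j & keep
      if (any(sel)) centers[j] <- sum(weights[sel] * x[sel]) / sum(weights[sel])
    }
  }
  o <- order(centers)
  cluster <- match(cluster, o)
  centers <- centers[o]
  sse <- sum(weights * (x - centers[cluster])^2)
  list(centers = centers, cluster = cluster, sse = sse, iter = it)
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Fit a Gaussian mixture to white intensities by EM
#'
#' Expectation-maximization for a k-component univariate Gaussian mixture,
#' initialized by quantile-seeded k-means and therefore deterministic by
#' default. Quantized data (integer grey levels) are collapsed to a weighted
#' histogram internally, which is mathematically identical to fitting the raw
#' pixels and much faster. The log-likelihood is nondecreasing at every
#' iteration; the trace is returned for inspection.
#'
#' @param x intensity values (typically positive pixels, i.e. <= t0), or bin
#'   midpoints when `weights` is given.
#' @param k number of components (default 3: strong, moderate, weak).
#' @param weights optional frequency weights (histogram counts).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap.
#' @param sigma_floor lower bound on component sd (grey levels), preventing
#'   collapse onto a single occupied bin.
#' @param weight_floor minimum mixing weight before a component is declared
#'   collapsed; a collapsed component is re-initialized once, then the fit
#'   fails with a diagnostic.
#' @param init "kmeans" (default) or a list(weights, means, sds) start.
#' @return a [mixture_model()] with `loglik`, `loglik_trace` and `iter`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 60, 10), rnorm(300, 150, 15))
#' fit_gmm_em(x, k = 2)
#' @export
fit_gmm_em <- function(x, k = 3L, weights = NULL, tol = 1e-6, max_iter = 500L,
                       sigma_floor = 0.5, weight_floor = 1e-4,
                       init = "kmeans") {
  x <- as.numeric(x)
  if (is.null(weights)) {
    # collapse quantized data to a histogram: identical likelihood, faster
    if (length(x) > 1000 && all(x == round(x))) {
      tab <- table(x)
      weights <- as.numeric(tab)
      x <- as.numeric(names(tab))
    } else weights <- rep(1, length(x))
  }
  n <- sum(weights)
  if (n < 10 * k) stop("need at least 10*k observations to fit the mixture")
  if (identical(init, "kmeans")) {
    km <- kmeans_1d(x, k, weights = weights)
    pi_s <- vapply(seq_len(k), function(j) sum(weights[km$cluster == j]) / n, numeric(1))
    mu <- km$centers
    sg <- vapply(seq_len(k), function(j) {
      sel <- km$cluster == j
      sqrt(sum(weights[sel] * (x[sel] - mu[j])^2) / max(sum(weights[sel]), 1))
    }, numeric(1))
  } else {
    pi_s <- init$weights; mu <- init$means; sg <- init$sds
  }
  sg <- pmax(sg, sigma_floor)
  pi_s <- pmax(pi_s, weight_floor); pi_s <- pi_s / sum(pi_s)

  em_pass <- function(pi_s, mu, sg) {
    trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(s)
        pi_s[s] * stats::dnorm(x, mu[s], sg[s]), numeric(length(x)))
      tot <- rowSums(dens)
      tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
      ll <- sum(weights * log(tot))
      trace <- c(trace, ll)
      r <- dens / tot                         # responsibilities
      wr <- r * weights
      ns <- colSums(wr)
      if (any(ns / n < weight_floor))
        return(list(collapsed = TRUE, which = which.min(ns)))
      pi_s <- ns / n
      mu <- colSums(wr * x) / ns
      sg <- vapply(seq_len(k), function(s)
        max(sqrt(sum(wr[, s] * (x - mu[s])^2) / ns[s]), sigma_floor), numeric(1))
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(collapsed = FALSE, weights = pi_s, means = mu, sds = sg,
         loglik = ll, trace = trace, iter = it)
  }

  res <- em_pass(pi_s, mu, sg)
  if (isTRUE(res$collapsed)) {
    # one re-initialization: respawn the collapsed component at the data median
    mu[res$which] <- weighted_quantile(x, weights, 0.5)
    sg[res$which] <- max(stats::sd(rep(x, times = pmin(weights, 1e4))), sigma_floor)
    pi_s <- rep(1 / k, k)
    res <- em_pass(pi_s, mu, sg)
    if (isTRUE(res$collapsed))
      stop(sprintf("EM component %d collapsed (weight < %g) even after re-initialization",
                   res$which, weight_floor))
  }
  m <- mixture_model(res$weights, res$means, res$sds,
                     loglik = res$loglik, iter = res$iter)
  m$loglik_trace <- res$trace
  m
}

#' Intersections of adjacent mixture components
#'
#' For each adjacent component pair solves
#' pi_s N(x; mu_s, sd_s) = pi_{s+1} N(x; mu_{s+1}, sd_{s+1}) -- a quadratic
#' in x -- and returns the root strictly between the two means. These
#' intersection points, projected onto the intensity axis, are the category
#' thresholds (t1, t2) for a 3-component model. If no quadratic root falls
#' between the means (extreme weight imbalance) the responsibility-equality
#' point is found by bisection instead.
#'
#' @param model a [mixture_model()] with strictly ascending means.
#' @param weighted use weight-scaled densities (default); `FALSE` intersects
#'   the unweighted component densities.
#' @return numeric vector of k-1 intersection points (for k = 3: c(t1, t2)).
#' @export
component_intersections <- function(model, weighted = TRUE) {
  k <- model$k
  if (any(diff(model$means) <= 0))
    stop("degenerate mixture: adjacent component means must differ")
  out <- vapply(seq_len(k - 1L), function(s) {
    p1 <- if (weighted) model$weights[s] else 1
    p2 <- if (weighted) model$weights[s + 1L] else 1
    gaussian_crossing(p1, model$means[s], model$sds[s],
                      p2, model$means[s + 1L], model$sds[s + 1L])
  }, numeric(1))
  if (k == 3L && out[1] >= out[2])
    stop("intersection ordering violated (t1 >= t2): mixture unsuitable for categorization")
  out
}

# root of p1*N(x;m1,s1) = p2*N(x;m2,s2) strictly inside (m1, m2), m1 < m2
gaussian_crossing <- function(p1, m1, s1, p2, m2, s2) {
  # log equality: x^2 (1/s2^2 - 1/s1^2)/2 + x (m1/s1^2 - m2/s2^2)
  #             + (m2^2/s2^2 - m1^2/s1^2)/2 + log(p1 s2 / (p2 s1)) = 0
  a <- (1 / s2^2 - 1 / s1^2) / 2
  b <- m1 / s1^2 - m2 / s2^2
  cc <- (m2^2 / s2^2 - m1^2 / s1^2) / 2 + log((p1 * s2) / (p2 * s1))
  roots <- if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside) >= 1L) return(inside[1])
  # fallback: responsibility-equality point by bisection on (m1, m2)
  f <- function(x) log(p1) + stats::dnorm(x, m1, s1, log = TRUE) -
    log(p2) - stats::dnorm(x, m2, s2, log = TRUE)
  lo <- m1 + 1e-9; hi <- m2 - 1e-9
  if (f(lo) * f(hi) > 0) return((m1 + m2) / 2)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Categorize staining intensities
#'
#' Assigns each white intensity to a category: strong (value <= t1), moderate
#' (t1 < value <= t2), weak (t2 < value <= t0), negative (value > t0) --
#' boundaries belong to the stronger side. Fractions are computed over
#' positive values by default, or over all values with
#' `denominator = "all"` (the remainder then being the negative fraction).
#'
#' @param values numeric white intensities.
#' @param thresholds a [category_thresholds()].
#' @param denominator "positive" (default) or "all".
#' @return list with `category` (factor: negative/weak/moderate/strong),
#'   `counts`, `fractions` (weak, moderate, strong), and `all_negative` flag
#'   (fractions are zero when no value is positive).
#' @export
categorize_intensities <- function(values, thresholds,
                                   denominator = c("positive", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(thresholds, "category_thresholds"))
  v <- as.numeric(values)
  cat_lev <- c("negative", "weak", "moderate", "strong")
  cat <- factor(ifelse(v > thresholds$t0, "negative",
               ifelse(v > thresholds$t2, "weak",
               ifelse(v > thresholds$t1, "moderate", "strong"))),
               levels = cat_lev)
  counts <- table(cat)
  n_pos <- sum(counts[c("weak", "moderate", "strong")])
  all_negative <- n_pos == 0L
  den <- if (denominator == "positive") n_pos else length(v)
  fractions <- if (den > 0)
    as.numeric(counts[c("weak", "moderate", "strong")]) / den
  else c(0, 0, 0)
  names(fractions) <- c("weak", "moderate", "strong")
  list(category = cat, counts = counts, fractions = fractions,
       all_negative = all_negative, denominator = denominator)
}

#' Calibrate category thresholds from positive DAB intensities
#'
#' The full calibration step: set t0 (Otsu on the 256-bin histogram, or a
#' fixed override such as 230), fit the 3-component mixture to values at or
#' below t0, and place t1, t2 at the component intersections.
#'
#' @param values DAB white intensities of a calibration field (pixels or
#'   per-cell means; integers 0..255 or reals).
#' @param t0 "auto" for Otsu, or a fixed numeric cutoff.
#' @param k number of mixture components.
#' @param weighted weight-scaled intersections (see
#'   [component_intersections()]).
#' @param ... passed to [fit_gmm_em()].
#' @return a [category_thresholds()] with the fitted `mixture_model` attached
#'   as attribute `model`.
#' @export
derive_thresholds <- function(values, t0 = "auto", k = 3L, weighted = TRUE, ...) {
  v <- as.numeric(values)
  t0v <- if (identical(t0, "auto")) {
    h <- tabulate(pmin(pmax(round(v), 0), 255) + 1L, nbins = 256L)
    global_threshold(h)
  } else as.numeric(t0)
  pos <- v[v <= t0v]
  model <- fit_gmm_em(pos, k = k, ...)
  ts <- component_intersections(model, weighted = weighted)
  th <- category_thresholds(t0 = t0v, t1 = ts[1], t2 = ts[2])
  attr(th, "model") <- model
  th
}
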