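#' Stain vector matrices for color deconvolution
#'
#' Builds the 3 x 3 optical-density stain matrix used to unmix an RGB
#' brightfield image into per-stain concentrations. Each column is the
#' unit-length optical-density triplet of one stain; the default is the
#' published Ruifrok-Johnston hematoxylin/DAB pair with the residual channel
#' completed as the normalized cross product of the two.
#'
#' @param hematoxylin,dab numeric(3), optical-density triplets (need not be
#'   pre-normalized; they are scaled to unit Euclidean length).
#' @param residual optional numeric(3) third stain; if `NULL` the complement
#'   of the first two columns is used.
#' @return a 3 x 3 matrix of class `stain_vectors`, columns named
#'   `hematoxylin`, `dab`, `residual`, rows `r`, `g`, `b`.
#' @examples
#' M <- hdab_stain_vectors()
#' colSums(M^2)  # all 1
#' @export
stain_vectors <- function(hematoxylin, dab, residual = NULL) {
  h <- as.numeric(hematoxylin)
  d <- as.numeric(dab)
  if (length(h) != 3L || length(d) != 3L)
    stop("stain vectors must have 3 components (r, g, b)")
  if (is.null(residual)) {
    # Ruifrok complement: per channel, the residual absorbs what the two
    # stains (normalized) leave of a unit OD vector
    hn <- h / sqrt(sum(h^2)); dn <- d / sqrt(sum(d^2))
    residual <- sqrt(pmax(1 - hn^2 - dn^2, 0))
  }
  r <- as.numeric(residual)
  M <- cbind(hematoxylin = h / sqrt(sum(h^2)),
             dab = d / sqrt(sum(d^2)),
             residual = r / sqrt(sum(r^2)))
  rownames(M) <- c("r", "g", "b")
  validate_stain_vectors(M)
  class(M) <- c("stain_vectors", class(M))
  M
}

validate_stain_vectors <- function(M) {
  if (!all(dim(M) == c(3L, 3L))) stop("stain matrix must be 3 x 3")
  if (any(M < -1e-9)) stop("stain vector entries must be non-negative")
  n <- sqrt(colSums(M^2))
  if (any(abs(n - 1) > 1e-6))
    stop("stain vector columns must have unit Euclidean norm")
  if (!is.finite(kappa(M)) || abs(det(M)) < 1e-12)
    stop("stain matrix is singular: ", paste(signif(M, 4), collapse = " "))
  invisible(M)
}

#' @rdname stain_vectors
#' @export
hdab_stain_vectors <- function() {
  stain_vectors(hematoxylin = c(0.650, 0.704, 0.286),
                dab = c(0.268, 0.570, 0.776))
}

#' Convert an RGB image to optical density
#'
#' OD_c = -log10((I_c + eps) / I0) per channel. `eps` guards the logarithm at
#' zero transmission; `od_to_rgb()` is its exact inverse (before rounding).
#'
#' @param img numeric array h x w x 3 with values in 0..255, or any numeric
#'   array of intensities.
#' @param I0 reference white level (default 255).
#' @param eps log guard, default 1/255.
#' @return array of the same shape with optical densities (>= 0 wherever
#'   I <= I0).
#' @export
rgb_to_od <- function(img, I0 = 255, eps = 1 / 255) {
  if (I0 <= 0) stop("I0 must be positive")
  -log10((img + eps) / I0)
}

#' @rdname rgb_to_od
#' @param od optical-density array.
#' @export
od_to_rgb <- function(od, I0 = 255, eps = 1 / 255) {
  I0 * 10^(-od) - eps
}

#' Unmix optical densities into stain concentrations
#'
#' Per pixel solves `vectors %*% c = OD` exactly. Concentrations may be
#' slightly negative under noise; they are preserved here and only clipped in
#' [concentration_to_white_intensity()].
#'
#' @param od h x w x 3 optical-density array.
#' @param vectors a [stain_vectors()] matrix.
#' @return h x w x 3 array of concentrations, third dimension named after the
#'   stains.
#' @export
deconvolve <- function(od, vectors = hdab_stain_vectors()) {
  validate_stain_vectors(vectors)
  d <- dim(od)
  if (length(d) != 3L || d[3] != 3L) stop("od must be an h x w x 3 array")
  flat <- matrix(od, ncol = 3L)            # pixels x channels
  conc <- t(solve(vectors, t(flat)))       # pixels x stains
  out <- array(conc, dim = d)
  dimnames(out) <- list(NULL, NULL, colnames(vectors))
  out
}

#' Compose stain concentrations back into optical density
#'
#' Forward model: OD = vectors %*% c, the Beer-Lambert superposition of
#' stains. Inverse of [deconvolve()] to numerical precision.
#'
#' @inheritParams deconvolve
#' @param conc h x w x 3 concentration array.
#' @export
compose_od <- function(conc, vectors = hdab_stain_vectors()) {
  validate_stain_vectors(vectors)
  d <- dim(conc)
  if (length(d) != 3L || d[3] != 3L) stop("conc must be an h x w x 3 array")
  flat <- matrix(conc, ncol = 3L)
  od <- flat %*% t(vectors)
  array(od, dim = d)
}

#' Map a stain concentration image to white pixel intensity
#'
#' w = clip(255 * 10^(-max(c, 0)), 0, 255), rounded to the nearest integer:
#' the exact inverse of the OD transform applied to a single stain, so 255
#' means "no stain" and low values mean strong staining -- the scale on which
#' all thresholds (t0, t1, t2) of this package live.
#'
#' @param conc numeric matrix/array of concentrations for one stain.
#' @param round round to integer grey levels (default TRUE).
#' @return same shape, white intensities in 0..255.
#' @export
concentration_to_white_intensity <- function(conc, round = TRUE) {
  w <- 255 * 10^(-pmax(conc, 0))
  w <- pmin(pmax(w, 0), 255)
  if (round) w <- round(w)
  w
}

#' Separate an RGB image into per-stain white-intensity images
#'
#' The full separation step: OD transform, linear unmixing, and conversion of
#' each stain concentration to the 0-255 white-intensity scale.
#'
#' @param img 8-bit RGB array (h x w x 3, values 0..255).
#' @inheritParams deconvolve
#' @param I0 reference white level.
#' @return named list of h x w integer matrices (`hematoxylin`, `dab`,
#'   `residual`).
#' @examples
#' img <- array(200, dim = c(4, 4, 3))
#' s <- separate_stains(img)
#' s$dab[1, 1]
#' @export
separate_stains <- function(img, vectors = hdab_stain_vectors(), I0 = 255) {
  conc <- deconvolve(rgb_to_od(img, I0 = I0), vectors)
  out <- lapply(seq_len(3L), function(s)
    concentration_to_white_intensity(conc[, , s]))
  names(out) <- colnames(vectors)
  out
}
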