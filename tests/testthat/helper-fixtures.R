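# shared fixtures: the calibration-field-like mixture and small image specs

fig_mixture <- function() {
  mixture_model(c(0.3, 0.4, 0.3), c(40, 130, 205), c(15, 25, 12))
}

small_image_spec <- function(...) {
  args <- utils::modifyList(list(width = 220L, height = 220L, n_cells = 50L,
                                 seed = 42L), list(...))
  do.call(synthetic_image_spec, args)
}

# exhaustive between-class variance maximizer: the independent Otsu oracle
otsu_brute_force <- function(counts) {
  counts <- c(counts, numeric(256 - length(counts)))
  n <- sum(counts)
  lev <- 0:255
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:254) {
    w0 <- sum(counts[1:(t + 1)]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:(t + 1)] * lev[1:(t + 1)]) / sum(counts[1:(t + 1)])
    m1 <- sum(counts[(t + 2):256] * lev[(t + 2):256]) / sum(counts[(t + 2):256])
    v <- w0 * w1 * (m0 - m1)^2
    if (!is.finite(best) || v > best + abs(best) * 1e-10) { best <- v; best_t <- t }
  }
  best_t
}

# dense-grid crossing search for weighted component densities
grid_intersection <- function(p1, m1, s1, p2, m2, s2, step = 0.001) {
  x <- seq(m1, m2, by = step)
  d <- p1 * dnorm(x, m1, s1) - p2 * dnorm(x, m2, s2)
  i <- which(diff(sign(d)) != 0)[1]
  (x[i] + x[i + 1]) / 2
}
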