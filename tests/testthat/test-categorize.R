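test_that("global threshold equals the exhaustive between-class-variance maximizer", {
  # two-spike histogram: any split between the spikes maximizes; tie -> smallest
  h <- numeric(256); h[50 + 1] <- 10; h[200 + 1] <- 10
  expect_identical(global_threshold(h), 50L)
  # single occupied bin: degenerate, flagged
  h1 <- numeric(256); h1[100 + 1] <- 5
  t1 <- global_threshold(h1)
  expect_equal(as.integer(t1), 100L)
  expect_true(isTRUE(attr(t1, "degenerate")))
  expect_error(global_threshold(numeric(256)), "empty")
  # override bypasses computation
  expect_identical(global_threshold(h, override = 230), 230L)
  # randomized oracle check
  set.seed(101)
  for (i in 1:300) {
    counts <- rpois(256, lambda = rexp(256, 1 / 5))
    if (sum(counts) == 0 || sum(counts > 0) < 2) next
    expect_identical(as.integer(global_threshold(counts)), otsu_brute_force(counts))
  }
})

test_that("1-D k-means finds obvious clusters and never increases SSE", {
  km <- kmeans_1d(c(rep(0, 10), rep(100, 10), rep(200, 10)), k = 3)
  expect_equal(km$centers, c(0, 100, 200))
  x <- c(1, 2, 8, 9, 20)
  expect_equal(kmeans_1d(x, k = 1)$centers, mean(x))
  expect_error(kmeans_1d(c(1, 1, 1), k = 2), "distinct")
  # SSE of the converged solution never exceeds the SSE at initialization
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(200, mean = sample(1:3, 200, replace = TRUE) * 50, sd = 10)
    km <- kmeans_1d(x, k = 3)
    init <- sort(quantile(x, c(1, 3, 5) / 6))
    d <- outer(x, as.numeric(init), function(a, b) (a - b)^2)
    sse_init <- sum(apply(d, 1, min))
    expect_lte(km$sse, sse_init + 1e-9)
    expect_true(all(diff(km$centers) > 0))
  }
})

test_that("EM recovers mixture parameters and is monotone in log-likelihood", {
  truth <- fig_mixture()
  x <- round(generate_mixture_sample(truth, 1e4, seed = 11))
  fit <- fit_gmm_em(x)
  expect_lt(max(abs(fit$means - truth$means)), 2)
  expect_true(all(diff(fit$loglik_trace) >= -1e-7))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$means) > 0))
  # thresholds close to the analytic intersections of the generating mixture
  expect_lt(max(abs(component_intersections(fit) - component_intersections(truth))), 3)
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  truth <- fig_mixture()
  x <- round(generate_mixture_sample(truth, 8000, seed = 19))
  fit <- fit_gmm_em(x)
  mc <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(sort(as.numeric(mc$parameters$mean)) - fit$means)), 2.5)
})

test_that("single-component EM is the closed-form fixed point", {
  set.seed(3)
  x <- rnorm(500, 120, 20)
  fit <- fit_gmm_em(x, k = 1)
  expect_equal(fit$means, mean(x), tolerance = 1e-8)
  expect_equal(fit$sds, sqrt(mean((x - mean(x))^2)), tolerance = 1e-6)
})

test_that("a 3-component fit to single-Gaussian data approximates that Gaussian", {
  set.seed(23)
  x <- round(rnorm(2e4, 130, 25))
  fit <- fit_gmm_em(x, k = 3)
  grid <- seq(0, 255, by = 0.05)
  tv <- 0.5 * sum(abs(mixture_density(fit, grid) - dnorm(grid, 130, 25))) * 0.05
  expect_lt(tv, 0.02)
})

test_that("parameter recovery holds across seeded replicates", {
  truth <- fig_mixture()
  true_ts <- component_intersections(truth)
  mu_err <- t_err <- numeric(20)
  for (r in 1:20) {
    x <- round(generate_mixture_sample(truth, 1e4, seed = 1000 + r))
    fit <- fit_gmm_em(x)
    mu_err[r] <- max(abs(fit$means - truth$means))
    t_err[r] <- max(abs(component_intersections(fit) - true_ts))
  }
  expect_lt(median(mu_err), 2)
  expect_lt(median(t_err), 3)
})

test_that("component intersections match closed forms and a grid search", {
  # equal weights, equal sds: exact midpoint
  m <- mixture_model(c(0.5, 0.5), c(50, 150), c(10, 10))
  expect_equal(component_intersections(m), 100, tolerance = 1e-9)
  # equal sds, unequal weights: analytic shift
  m2 <- mixture_model(c(0.7, 0.3), c(50, 150), c(12, 12))
  expected <- (50 + 150) / 2 + 12^2 * log(0.7 / 0.3) / (150 - 50)
  expect_equal(component_intersections(m2), expected, tolerance = 1e-9)
  # unequal sds: agrees with a dense-grid density-crossing search
  set.seed(31)
  for (i in 1:15) {
    mu <- sort(runif(2, 30, 220)); if (diff(mu) < 20) next
    sg <- runif(2, 5, 25); pw <- runif(1, 0.2, 0.8)
    m3 <- mixture_model(c(pw, 1 - pw), mu, sg)
    got <- component_intersections(m3)
    ref <- grid_intersection(pw, mu[1], sg[1], 1 - pw, mu[2], sg[2])
    if (!is.na(ref)) expect_lt(abs(got - ref), 0.01)
  }
  # unweighted mode drops the mixing weights
  expect_equal(component_intersections(m2, weighted = FALSE), 100, tolerance = 1e-9)
  expect_error(component_intersections(mixture_model(c(.5, .5), c(100, 100.0), c(5, 5))),
               "degenerate|ascending")
})

test_that("intensities are categorized with boundaries on the stronger side", {
  th <- category_thresholds(t0 = 230, t1 = 85, t2 = 180)
  res <- categorize_intensities(c(40, 120, 200, 250), th)
  expect_equal(as.character(res$category), c("strong", "moderate", "weak", "negative"))
  # exact boundary values go to the stronger side
  res_b <- categorize_intensities(c(85, 180, 230), th)
  expect_equal(as.character(res_b$category), c("strong", "moderate", "weak"))
  # all negative: zero fractions plus flag
  res_n <- categorize_intensities(c(240, 250), th)
  expect_true(res_n$all_negative)
  expect_equal(unname(res_n$fractions), c(0, 0, 0))
  # fractions sum to 1 over the chosen denominator
  res_a <- categorize_intensities(c(40, 120, 200, 250), th, denominator = "all")
  expect_equal(sum(res_a$fractions), 0.75)
  expect_equal(sum(res$fractions), 1)
  expect_error(category_thresholds(230, 180, 85), "invalid")
})

test_that("threshold calibration runs end to end on sampled intensities", {
  truth <- fig_mixture()
  set.seed(77)
  x <- round(c(generate_mixture_sample(truth, 8000, seed = 77),
               rnorm(24000, 248, 3)))  # positives under a dominant background
  x <- pmin(pmax(x, 0), 255)
  th <- derive_thresholds(x, t0 = 230)
  expect_s3_class(th, "category_thresholds")
  expect_true(th$t1 < th$t2 && th$t2 < th$t0)
  expect_lt(max(abs(c(th$t1, th$t2) - component_intersections(truth))), 4)
  expect_s3_class(attr(th, "model"), "mixture_model")
  # automatic t0 still yields a valid ordered threshold set
  th_auto <- derive_thresholds(x, t0 = "auto")
  expect_true(th_auto$t1 < th_auto$t2 && th_auto$t2 < th_auto$t0)
  expect_identical(as.integer(th_auto$t0),
                   otsu_brute_force(tabulate(x + 1L, nbins = 256L)))
})
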