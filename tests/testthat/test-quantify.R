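test_that("segmentation recovers well-separated synthetic nuclei", {
  gt <- generate_ihc_image(small_image_spec(noise_sd = 0))
  ch <- separate_stains(gt$image, gt$spec$vectors)
  seg <- segment_nuclei(ch$hematoxylin, min_area = 20L)
  expect_equal(max(seg), nrow(gt$cells))
  # each segmented nucleus overlaps exactly one ground-truth cell with IoU > 0.7
  for (lab in seq_len(max(seg))) {
    truth_labels <- gt$mask[seg == lab]
    truth_labels <- truth_labels[truth_labels > 0]
    expect_length(unique(truth_labels), 1)
    tl <- truth_labels[1]
    inter <- sum(seg == lab & gt$mask == tl)
    union <- sum(seg == lab | gt$mask == tl)
    expect_gt(inter / union, 0.7)
  }
  # blank image and oversized min_area give empty masks
  expect_equal(max(segment_nuclei(matrix(255, 40, 40))), 0L)
  expect_equal(max(segment_nuclei(ch$hematoxylin, min_area = 1e5)), 0L)
})

test_that("nucleus positivity follows the t0 rule including the boundary", {
  mask <- matrix(0L, 4, 6)
  mask[1:2, 1:2] <- 1L; mask[3:4, 4:6] <- 2L
  dab <- matrix(255, 4, 6)
  dab[mask == 1L] <- 230   # mean exactly t0 -> positive
  dab[mask == 2L] <- 231
  rec <- nucleus_positivity(dab, mask, t0 = 230)
  expect_equal(rec$positive, c(TRUE, FALSE))
  expect_equal(rec$area, c(4L, 6L))
  # all-background image: nothing positive
  rec2 <- nucleus_positivity(matrix(255, 4, 6), mask, t0 = 230)
  expect_false(any(rec2$positive))
})

test_that("percent positive summarizes fields correctly", {
  p <- percent_positive(c(rep(TRUE, 35), rep(FALSE, 65)))
  expect_equal(p$mean, 35)
  two <- percent_positive(c(rep(TRUE, 3), rep(FALSE, 7), rep(TRUE, 4), rep(FALSE, 6)),
                          field = rep(1:2, each = 10))
  expect_equal(two$mean, 35)
  expect_equal(two$sd, sd(c(30, 40)), tolerance = 1e-9)
  all_pos <- percent_positive(rep(TRUE, 10), field = rep(1:2, each = 5))
  expect_equal(all_pos$mean, 100); expect_equal(all_pos$sd, 0)
  expect_error(percent_positive(logical(0)), "empty")
})

test_that("region mean intensity respects the pixel-selection mode", {
  dab <- matrix(c(rep(100, 50), rep(250, 50)), 10, 10)
  region <- matrix(TRUE, 10, 10)
  expect_equal(region_mean_intensity(dab, region, 230)$mean, 100)
  expect_equal(region_mean_intensity(dab, region, 230, mode = "all")$mean, 175)
  uni <- matrix(100, 5, 5)
  expect_equal(region_mean_intensity(uni, uni > 0, 230)$mean, 100)
  nopos <- region_mean_intensity(matrix(250, 5, 5), matrix(TRUE, 5, 5), 230)
  expect_true(nopos$no_positive); expect_true(is.na(nopos$mean))
})

test_that("the weighted score is bounded, monotone and conserves counts", {
  expect_equal(weighted_score(c(0, 0, 1)), 3)
  expect_equal(weighted_score(c(0, 0, 0)), 0)
  expect_equal(weighted_score(c(1, 1, 1) / 3), 2)
  expect_error(weighted_score(c(0.6, 0.6, 0)), "at most 1")
  expect_error(weighted_score(c(-0.1, 0.5, 0.5)), "non-negative")
  set.seed(12)
  for (i in 1:50) {
    f <- runif(3); f <- f / sum(f) * runif(1)
    s <- weighted_score(f)
    expect_gte(s, 0); expect_lte(s, 3)
    # moving mass from weak to strong never decreases the score
    delta <- f[1] * runif(1)
    expect_gte(weighted_score(f + c(-delta, 0, delta)), s - 1e-12)
  }
})

test_that("end-to-end scoring matches synthetic ground truth", {
  gt <- generate_ihc_image(small_image_spec(n_cells = 60L, seed = 21L))
  ch <- separate_stains(gt$image, gt$spec$vectors)
  res <- score_regions(ch, gt$thresholds)
  truth_counts <- table(gt$cells$category)
  # counting conservation
  expect_equal(res$n_negative + res$n_weak + res$n_moderate + res$n_strong,
               res$n_cells)
  expect_equal(res$n_cells, nrow(gt$cells))
  # zero noise: category counts exact
  expect_equal(c(res$n_negative, res$n_weak, res$n_moderate, res$n_strong),
               as.numeric(truth_counts[c("negative", "weak", "moderate", "strong")]))
  truth_pct <- 100 * mean(gt$cells$category != "negative")
  expect_lt(abs(res$pct_positive - truth_pct), 2)
  expect_gte(res$score, 0); expect_lte(res$score, 3)
})

test_that("baseline normalization maps time zero to 100 and errors on missing baselines", {
  tc <- generate_timecourse(seed = 3)
  nb <- normalize_to_baseline(tc)
  t0mean <- tapply(nb$value_pct[nb$time_h == 0],
                   nb$case[nb$time_h == 0], mean)
  expect_equal(as.numeric(t0mean), rep(100, 9), tolerance = 1e-9)
  # constant values: 100% everywhere
  const <- data.frame(case = 1, marker = "ER", time_h = rep(c(0, 1, 6, 24), each = 2),
                      field = rep(1:2, 4), value = 80)
  expect_true(all(abs(normalize_to_baseline(const)$value_pct - 100) < 1e-12))
  # arithmetic: baseline mean 80, 1-h mean 68 -> 85%
  d <- data.frame(case = 1, marker = "ER", time_h = c(0, 1), field = 1,
                  value = c(80, 68))
  expect_equal(normalize_to_baseline(d)$value_pct, c(100, 85))
  missing <- data.frame(case = 2, marker = "ER", time_h = 1, field = 1, value = 5)
  expect_error(normalize_to_baseline(missing), "case 2")
})

test_that("percent CV matches its definition and flags a zero mean", {
  expect_equal(percent_cv(c(5, 5, 5)), 0)
  expect_equal(percent_cv(c(90, 110)), 100 * sd(c(90, 110)) / 100)
  expect_equal(percent_cv(c(90, 110)), 14.14, tolerance = 1e-3)
  expect_true(is.na(percent_cv(c(-1, 1))))
  expect_error(percent_cv(5), "at least 2")
  # generator with 5% field CV lands inside the empirically observed 0.2-11% band
  tc <- generate_timecourse(field_cv = 0.05, seed = 6)
  cvs <- tapply(tc$value, interaction(tc$case, tc$time_h),
                function(v) percent_cv(v))
  expect_true(all(cvs > 0.2 & cvs < 11))
  expect_lt(abs(median(cvs) - 5), 2)
})
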