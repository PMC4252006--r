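#' One-way ANOVA across time groups
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test).
#'
#' @param groups list of numeric vectors, one per group (each n >= 2).
#' @return list with `statistic` (F), `df`, `p`, `test`.
#' @export
anova_oneway <- function(groups) {
  check_groups(groups, min_n = 2L)
  d <- groups_to_df(groups)
  if (stats::var(d$value) == 0)
    return(list(statistic = NA_real_, df = c(length(groups) - 1L,
                                             nrow(d) - length(groups)),
                p = NA_real_, test = "one-way ANOVA", degenerate = TRUE))
  ft <- stats::oneway.test(value ~ group, data = d, var.equal = TRUE)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value, test = "one-way ANOVA")
}

#' Welch's ANOVA on rank-transformed data
#'
#' Pools all observations, replaces them by mid-ranks, then applies Welch's
#' heteroscedasticity-robust one-way ANOVA -- the confirmation test used
#' alongside the classical ANOVA.
#'
#' @inheritParams anova_oneway
#' @return list with `statistic`, `df`, `p`, `test`.
#' @export
welch_anova_on_ranks <- function(groups) {
  check_groups(groups, min_n = 2L)
  d <- groups_to_df(groups)
  d$value <- rank(d$value, ties.method = "average")
  if (stats::var(d$value) == 0)
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                test = "Welch ANOVA on ranks", degenerate = TRUE))
  ft <- stats::oneway.test(value ~ group, data = d, var.equal = FALSE)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value, test = "Welch ANOVA on ranks")
}

#' Tukey studentized-range pairwise comparisons
#'
#' Tukey's honest significant difference test after a one-way ANOVA,
#' controlling the familywise type-1 error across all group pairs.
#'
#' @inheritParams anova_oneway
#' @param alpha familywise significance level.
#' @return data.frame with `pair`, `diff`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  check_groups(groups, min_n = 2L)
  d <- groups_to_df(groups)
  tk <- stats::TukeyHSD(stats::aov(value ~ group, data = d))$group
  data.frame(pair = rownames(tk), diff = tk[, "diff"], p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha, row.names = NULL)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference distribution --
#' the nonparametric alternative used for markers with non-normal
#' distributions.
#'
#' @inheritParams anova_oneway
#' @return list with `statistic` (H), `df`, `p`, `test`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups, min_n = 1L)
  if (sum(lengths(groups)) < 3L) stop("need at least 3 observations in total")
  d <- groups_to_df(groups)
  if (stats::var(d$value) == 0)
    return(list(statistic = NA_real_, df = length(groups) - 1L, p = NA_real_,
                test = "Kruskal-Wallis", degenerate = TRUE))
  kt <- stats::kruskal.test(value ~ group, data = d)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, test = "Kruskal-Wallis")
}

#' Pairwise Wilcoxon rank-sum tests at a Bonferroni-adjusted level
#'
#' Two-sided Wilcoxon rank-sum tests for all m = choose(k, 2) group pairs;
#' each pair is called significant when its unadjusted p falls below
#' alpha / m. With four time points m = 6 and the per-pair level is
#' 0.05 / 6 = 0.0083 (as conventionally printed to four decimals). The exact
#' null distribution is used when the combined sample size of a pair is at
#' most 20 and there are no ties; otherwise the normal approximation with
#' continuity and tie correction.
#'
#' @inheritParams anova_oneway
#' @param alpha familywise significance level (default 0.05).
#' @return list with `m`, `level` (alpha/m), `level_printed` (rounded to 4
#'   decimals), and `pairs` (data.frame pair, statistic, p, significant).
#' @export
pairwise_wilcoxon_bonferroni <- function(groups, alpha = 0.05) {
  check_groups(groups, min_n = 1L)
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  m <- choose(k, 2L)
  level <- alpha / m
  combos <- utils::combn(k, 2L)
  rows <- apply(combos, 2L, function(ij) {
    a <- groups[[ij[1]]]; b <- groups[[ij[2]]]
    has_ties <- anyDuplicated(c(a, b)) > 0L
    wt <- suppressWarnings(stats::wilcox.test(
      a, b, exact = (length(a) + length(b) <= 20L) && !has_ties,
      correct = TRUE))
    # "level2-level1" labels, matching TukeyHSD's pair naming
    data.frame(pair = paste(nm[ij[2]], nm[ij[1]], sep = "-"),
               statistic = unname(wt$statistic), p = wt$p.value,
               significant = wt$p.value < level)
  })
  list(m = m, level = level, level_printed = round(level, 4),
       pairs = do.call(rbind, rows))
}

#' Full statistical battery for a decalcification time course
#'
#' Normalizes field measurements of one marker to each case's time-zero mean
#' (unless `normalize = FALSE`), groups them by decalcification time, and
#' runs the whole battery: one-way ANOVA confirmed by Welch's ANOVA on
#' ranks with Tukey pairwise comparisons (the parametric branch used for
#' approximately normal markers), plus Kruskal-Wallis with pairwise
#' Bonferroni-adjusted Wilcoxon tests (the nonparametric branch).
#'
#' @param table time-course data.frame (case, marker, time_h, field, value).
#' @param marker marker to analyse (default: the only marker present).
#' @param normalize express values as percent of the case baseline first.
#' @param alpha significance level.
#' @return list of class `decal_battery`: `marker`, `groups` (values per
#'   time), `anova`, `welch_ranks`, `tukey`, `kruskal`, `wilcoxon`, and
#'   `pairwise` -- a data.frame with one row per time pair combining the
#'   Tukey adjusted p and the Wilcoxon p, with a `significant` flag from the
#'   parametric (Tukey) branch.
#' @export
decal_battery <- function(table, marker = NULL, normalize = TRUE,
                          alpha = 0.05) {
  if (is.null(marker)) {
    marker <- unique(table$marker)
    if (length(marker) != 1L) stop("several markers present; pick one")
  }
  d <- table[table$marker == marker, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for marker ", marker)
  if (normalize) {
    d <- normalize_to_baseline(d)
    val <- d$value_pct
  } else val <- d$value
  groups <- split(val, d$time_h)
  res <- list(marker = marker, normalized = normalize, groups = groups,
              anova = anova_oneway(groups),
              welch_ranks = welch_anova_on_ranks(groups),
              tukey = tukey_hsd(groups, alpha = alpha),
              kruskal = kruskal_wallis(groups),
              wilcoxon = pairwise_wilcoxon_bonferroni(groups, alpha = alpha))
  pw <- merge(res$tukey[, c("pair", "p_adj", "significant")],
              res$wilcoxon$pairs[, c("pair", "p")],
              by = "pair", all = TRUE, suffixes = c("_tukey", "_wilcoxon"))
  names(pw) <- c("pair", "tukey_p_adj", "significant", "wilcoxon_p")
  res$pairwise <- pw
  class(res) <- "decal_battery"
  res
}

#' @export
print.decal_battery <- function(x, ...) {
  cat(sprintf("Decalcification battery for %s (%s values)\n", x$marker,
              if (x$normalized) "baseline-normalized" else "raw"))
  cat(sprintf("  ANOVA F = %.3f, p = %.4g; Welch-on-ranks p = %.4g; Kruskal-Wallis p = %.4g\n",
              x$anova$statistic, x$anova$p, x$welch_ranks$p, x$kruskal$p))
  cat(sprintf("  Wilcoxon per-pair level %.4f (m = %d)\n",
              x$wilcoxon$level_printed, x$wilcoxon$m))
  print(x$pairwise)
  invisible(x)
}

check_groups <- function(groups, min_n = 1L) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of at least 2 numeric vectors")
  if (any(lengths(groups) < min_n))
    stop("each group needs at least ", min_n, " observations")
  invisible(groups)
}

groups_to_df <- function(groups) {
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_along(groups))
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(nm, lengths(groups)), levels = nm))
}

# tukey pair naming uses the same order as TukeyHSD: "level2-level1"
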