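#' Welch's t-test from summary statistics
#'
#' Two-sided Welch (unequal variances) test computed directly from group
#' means, standard errors of the mean and sizes — the form needed to test
#' published summary tables: `t = (m1 - m2) / sqrt(sem1^2 + sem2^2)` with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param mean1,sem1,n1 First group's mean, SEM and size.
#' @param mean2,sem2,n2 Second group's mean, SEM and size.
#' @return A one-row tibble with `statistic`, `df`, `p_value`.
#' @examples
#' welch_t_from_summary(9.46, 0.75, 24, 14.31, 1.01, 22)
#' @export
welch_t_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  assert_that(n1 >= 2 && n2 >= 2, "Welch's t-test needs n >= 2 per group")
  assert_that(sem1 > 0 || sem2 > 0, "at least one group must have a positive SEM")
  v1 <- sem1^2; v2 <- sem2^2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  tibble::tibble(statistic = t, df = df, p_value = p)
}

#' Welch's t-test from raw samples
#'
#' Identical, by construction, to [welch_t_from_summary()] applied to the
#' computed group summaries.
#'
#' @param samples1,samples2 Numeric vectors, each of length >= 2.
#' @return A one-row tibble with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(samples1, samples2) {
  assert_that(length(samples1) >= 2 && length(samples2) >= 2,
              "Welch's t-test needs >= 2 values per group")
  s1 <- stats::sd(samples1); s2 <- stats::sd(samples2)
  assert_that(s1 > 0 || s2 > 0, "both groups have zero variance")
  welch_t_from_summary(mean(samples1), s1 / sqrt(length(samples1)), length(samples1),
                       mean(samples2), s2 / sqrt(length(samples2)), length(samples2))
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition over two or more
#' groups. With exactly two groups the F statistic equals the square of the
#' pooled-variance t statistic.
#'
#' @param ... Numeric vectors (one per group), or a single list of them.
#' @return A one-row tibble with `statistic` (F), `df1`, `df2`, `p_value`.
#' @examples
#' anova_oneway(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7))
#' @export
anova_oneway <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]])) groups <- groups[[1]]
  assert_that(length(groups) >= 2, "ANOVA needs at least two groups")
  assert_that(all(vapply(groups, length, integer(1)) >= 2),
              "ANOVA needs >= 2 values per group")
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  grand <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  assert_that(ssw > 0, "zero within-group variance; ANOVA F is undefined")
  df1 <- k - 1; df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  tibble::tibble(statistic = f, df1 = df1, df2 = df2,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Compare two proportions (2x2 table)
#'
#' Odds ratio plus three p-values for a `k1/n1` vs `k2/n2` comparison:
#' Fisher's exact two-sided p by full hypergeometric enumeration (summing
#' all tables whose point probability does not exceed the observed one —
#' the standard "small-p" rule), and the chi-square p with and without the
#' Yates continuity correction. Both chi-square variants are reported
#' because published incidence p-values often do not say which was used.
#'
#' @param k1,n1 Events and size in group 1.
#' @param k2,n2 Events and size in group 2.
#' @return A one-row tibble with `odds_ratio`, `p_fisher`, `p_chi2`,
#'   `p_chi2_yates`.
#' @examples
#' proportion_compare(10, 24, 1, 22)
#' @export
proportion_compare <- function(k1, n1, k2, n2) {
  assert_that(n1 > 0 && n2 > 0, "group sizes must be positive")
  assert_that(k1 >= 0 && k1 <= n1 && k2 >= 0 && k2 <= n2, "need 0 <= k <= n")
  a <- k1; b <- n1 - k1; c <- k2; d <- n2 - k2
  or <- (a * d) / (b * c)
  # hypergeometric enumeration conditional on all margins
  m <- a + c                      # total events
  support <- max(0, m - n2):min(m, n1)
  probs <- stats::dhyper(support, n1, n2, m)
  p_obs <- stats::dhyper(a, n1, n2, m)
  p_fisher <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  chi <- suppressWarnings(
    stats::chisq.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                      correct = FALSE))
  chi_y <- suppressWarnings(
    stats::chisq.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                      correct = TRUE))
  tibble::tibble(odds_ratio = or, p_fisher = min(p_fisher, 1),
                 p_chi2 = chi$p.value, p_chi2_yates = chi_y$p.value)
}

#' Incidence proportion
#'
#' `100 k / n` percent; the displayed value is rounded to one decimal the
#' way clinical tables print it, the exact value is retained.
#'
#' @param k Event count.
#' @param n Group size (> 0).
#' @return A one-row tibble with `events`, `n`, `incidence_pct` (exact) and
#'   `display_pct` (rounded to one decimal).
#' @examples
#' incidence(10, 24)  # 41.7%
#' @export
incidence <- function(k, n) {
  assert_that(n > 0, "n must be > 0")
  assert_that(k >= 0 && k <= n, "need 0 <= k <= n")
  pct <- 100 * k / n
  tibble::tibble(events = k, n = n, incidence_pct = pct,
                 display_pct = round(pct, 1))
}

#' Sample size for comparing two proportions
#'
#' Smallest integer n per group to detect `p1` vs `p2` at two-sided level
#' `alpha` with the given power, under a selectable normal-approximation
#' method: `"unpooled-normal"`
#' (`(z_{1-a/2} + z_{pow})^2 (p1 q1 + p2 q2) / (p1 - p2)^2`),
#' `"pooled-normal"` (pooled variance under H0 for the alpha term), or
#' `"arcsine"` (Cohen's effect size h). Different conventions give visibly
#' different n for the same inputs, which is why the method is explicit in
#' the output.
#'
#' @param p1,p2 The two proportions (0 < p2 < p1 < 1).
#' @param alpha Two-sided type I error.
#' @param power Target power.
#' @param method One of `"unpooled-normal"`, `"pooled-normal"`,
#'   `"arcsine"`.
#' @return A one-row tibble with `method`, `n_per_group` and the exact
#'   (unrounded) `n_exact`.
#' @examples
#' sample_size_two_proportions(0.35, 0.05)
#' @export
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.80,
                                        method = c("unpooled-normal",
                                                   "pooled-normal", "arcsine")) {
  method <- match.arg(method)
  assert_that(p1 > 0 && p1 < 1 && p2 > 0 && p2 < 1, "proportions must be in (0, 1)")
  assert_that(p1 != p2, "p1 must differ from p2 (otherwise n is infinite)")
  assert_that(alpha > 0 && alpha < 1 && power > 0 && power < 1,
              "alpha and power must be in (0, 1)")
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n_exact <- switch(method,
    "unpooled-normal" = (za + zb)^2 * (p1 * (1 - p1) + p2 * (1 - p2)) / (p1 - p2)^2,
    "pooled-normal" = {
      pbar <- (p1 + p2) / 2
      (za * sqrt(2 * pbar * (1 - pbar)) +
         zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
    },
    "arcsine" = {
      h <- abs(2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2)))
      ((za + zb) / h)^2
    }
  )
  tibble::tibble(method = method, n_per_group = as.integer(ceiling(n_exact - 1e-9)),
                 n_exact = n_exact)
}

#' Feature-by-feature group comparison table
#'
#' The machine twin of a published qEEG characteristics table: one row per
#' feature with each group's mean +/- SEM and the two-group Welch p-value
#' (or one-way ANOVA when three or more groups are present). Row order is
#' fixed to the conventional table layout: SE, aEEG upper, aEEG lower, RAV,
#' delta, theta, alpha, beta, SEF95.
#'
#' @param features A tibble of per-subject features as returned by
#'   [cohort_features()] (one row per subject).
#' @param group_col Name of the grouping column.
#' @param feature_cols Feature columns to compare; defaults to the nine
#'   standard qEEG features present in the input.
#' @param holm Also report Holm-adjusted p-values (off by default, matching
#'   the single-look convention of exploratory qEEG tables).
#' @return A `qeeg_comparison` tibble: `feature`, a `summaries` list column
#'   of per-group tibbles (`label`, `n`, `mean`, `sd`, `sem`), `test`,
#'   `statistic`, `df`, `df2`, `p_value` (and `p_holm` if requested).
#' @export
summarize_groups <- function(features, group_col = "group_label",
                             feature_cols = NULL, holm = FALSE) {
  assert_that(group_col %in% names(features),
              sprintf("no grouping column '%s' in features", group_col))
  canonical <- c("se", "aeeg_upper_uv", "aeeg_lower_uv", "rav_pct", "delta_pct",
                 "theta_pct", "alpha_pct", "beta_pct", "sef95_hz")
  if (is.null(feature_cols)) feature_cols <- intersect(canonical, names(features))
  assert_that(length(feature_cols) >= 1, "no feature columns found")
  labels <- unique(features[[group_col]])
  assert_that(length(labels) >= 2, "need at least two groups")
  sizes <- table(features[[group_col]])
  assert_that(all(sizes >= 2), "every group needs >= 2 subjects (SEM undefined otherwise)")

  rows <- purrr::map_dfr(feature_cols, function(fc) {
    by_group <- purrr::map_dfr(labels, function(lb) {
      v <- features[[fc]][features[[group_col]] == lb]
      tibble::tibble(label = lb, n = length(v), mean = mean(v),
                     sd = stats::sd(v), sem = stats::sd(v) / sqrt(length(v)))
    })
    if (length(labels) == 2) {
      tst <- welch_t_test(features[[fc]][features[[group_col]] == labels[1]],
                          features[[fc]][features[[group_col]] == labels[2]])
      tibble::tibble(feature = fc, summaries = list(by_group), test = "welch",
                     statistic = tst$statistic, df = tst$df, df2 = NA_real_,
                     p_value = tst$p_value)
    } else {
      grp <- purrr::map(labels, ~features[[fc]][features[[group_col]] == .x])
      tst <- anova_oneway(grp)
      tibble::tibble(feature = fc, summaries = list(by_group), test = "anova",
                     statistic = tst$statistic, df = tst$df1, df2 = tst$df2,
                     p_value = tst$p_value)
    }
  })
  if (holm) rows$p_holm <- stats::p.adjust(rows$p_value, method = "holm")
  class(rows) <- c("qeeg_comparison", class(rows))
  rows
}

#' @export
print.qeeg_comparison <- function(x, ...) {
  cat("<qeeg_comparison> ", nrow(x), " features\n\n", sep = "")
  wide <- tidy.qeeg_comparison(x) |>
    dplyr::mutate(cell = sprintf("%.2f ± %.2f", .data$mean, .data$sem)) |>
    dplyr::select("feature", "label", "cell") |>
    tidyr::pivot_wider(names_from = "label", values_from = "cell") |>
    dplyr::left_join(dplyr::select(tibble::as_tibble(x), "feature", "p_value"),
                     by = "feature") |>
    dplyr::mutate(p_value = sprintf("%.4f", .data$p_value))
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' Tidy a comparison table into long form
#'
#' @param x A `qeeg_comparison` from [summarize_groups()].
#' @param ... Unused.
#' @return Long tibble: one row per feature x group with `n`, `mean`, `sd`,
#'   `sem`, plus the test columns.
#' @method tidy qeeg_comparison
#' @export
tidy.qeeg_comparison <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("feature", "summaries", "test", "statistic", "p_value") |>
    tidyr::unnest("summaries")
}

#' One-line summary of a comparison table
#'
#' @param x A `qeeg_comparison`.
#' @param ... Unused.
#' @return One-row tibble: number of features, groups, the test used and
#'   how many features fall below p = 0.05.
#' @method glance qeeg_comparison
#' @export
glance.qeeg_comparison <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_groups = nrow(x$summaries[[1]]),
    test = x$test[1],
    n_significant = sum(x$p_value < 0.05)
  )
}
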