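test_that("Welch t from summaries matches closed forms and the CDF oracle", {
  same <- welch_t_from_summary(3, 0.5, 10, 3, 0.5, 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  r <- welch_t_from_summary(0, 1, 10, 1, 1, 10)
  expect_equal(r$statistic, -1 / sqrt(2), tolerance = 1e-9)
  expect_equal(r$df, 18, tolerance = 1e-9)
  expect_equal(r$p_value, 2 * stats::pt(-1 / sqrt(2), 18), tolerance = 1e-12)

  expect_error(welch_t_from_summary(0, 1, 1, 1, 1, 10), "n >= 2")
})

test_that("Welch t on raw samples equals the summary form and stats::t.test", {
  set.seed(14)
  for (i in 1:5) {
    a <- stats::rnorm(6 + i); b <- stats::rnorm(9, mean = 0.5)
    mine <- welch_t_test(a, b)
    summ <- welch_t_from_summary(mean(a), stats::sd(a) / sqrt(length(a)), length(a),
                                 mean(b), stats::sd(b) / sqrt(length(b)), length(b))
    expect_identical(mine, summ)
    oracle <- stats::t.test(a, b)
    expect_equal(mine$statistic, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(oracle$parameter), tolerance = 1e-12)
    expect_equal(mine$p_value, oracle$p.value, tolerance = 1e-12)
    # permutation within groups and swapping group order
    expect_identical(welch_t_test(sample(a), sample(b)), mine)
    swapped <- welch_t_test(b, a)
    expect_equal(swapped$statistic, -mine$statistic, tolerance = 1e-12)
    expect_equal(swapped$p_value, mine$p_value, tolerance = 1e-12)
  }
})

test_that("hand-computed Welch example: (1,2,3) vs (4,5,6)", {
  r <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(r$df, 4, tolerance = 1e-9)
  expect_equal(r$p_value, 2 * stats::pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(r$p_value, 0.0213, tolerance = 1e-3)
})

test_that("one-way ANOVA matches hand-computed sums of squares and oneway.test", {
  r <- anova_oneway(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7))
  expect_equal(r$statistic, 13, tolerance = 1e-12)
  expect_equal(c(r$df1, r$df2), c(2, 6))
  expect_equal(r$p_value, stats::pf(13, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  oracle <- stats::oneway.test(y ~ g, data = data.frame(
    y = c(1, 2, 3, 2, 3, 4, 5, 6, 7), g = rep(letters[1:3], each = 3)),
    var.equal = TRUE)
  expect_equal(r$statistic, unname(oracle$statistic), tolerance = 1e-12)

  flat <- anova_oneway(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(anova_oneway(c(2, 2), c(2, 2)), "zero within-group variance")
})

test_that("two-group ANOVA equals the squared pooled t-test", {
  set.seed(8)
  a <- stats::rnorm(8); b <- stats::rnorm(8, 1)
  f <- anova_oneway(a, b)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(f$statistic, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(f$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("Fisher enumeration: identity, exact 1/3 case, agreement with fisher.test", {
  r <- proportion_compare(5, 10, 5, 10)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_fisher, 1)

  # support {0,1,2} with probabilities 1/6, 4/6, 1/6: two-sided p = 1/3
  r2 <- proportion_compare(2, 2, 0, 2)
  expect_equal(r2$p_fisher, 1 / 3, tolerance = 1e-12)

  for (tab in list(c(10, 24, 1, 22), c(3, 9, 7, 11), c(0, 5, 4, 6))) {
    mine <- proportion_compare(tab[1], tab[2], tab[3], tab[4])
    oracle <- stats::fisher.test(matrix(c(tab[1], tab[2] - tab[1],
                                          tab[3], tab[4] - tab[3]),
                                        nrow = 2, byrow = TRUE))
    expect_equal(mine$p_fisher, oracle$p.value, tolerance = 1e-9)
  }
})

test_that("hypergeometric enumeration probabilities sum to one", {
  for (tab in list(c(10, 24, 1, 22), c(2, 2, 0, 2), c(8, 15, 3, 20))) {
    m <- tab[1] + tab[3]
    support <- max(0, m - tab[4]):min(m, tab[2])
    expect_equal(sum(stats::dhyper(support, tab[2], tab[4], m)), 1,
                 tolerance = 1e-12)
  }
})

test_that("the delirium incidence contrast is significant by every reported test", {
  r <- proportion_compare(10, 24, 1, 22)
  expect_lt(r$p_fisher, 0.01)
  expect_lt(r$p_chi2, 0.01)
  expect_gt(r$odds_ratio, 1)
})

test_that("incidence arithmetic reproduces printed one-decimal percentages", {
  expect_equal(incidence(10, 24)$display_pct, 41.7)
  expect_equal(incidence(1, 22)$display_pct, 4.5)
  expect_equal(incidence(0, 22)$display_pct, 0)
  expect_equal(incidence(10, 24)$incidence_pct, 1000 / 24, tolerance = 1e-12)
  expect_error(incidence(3, 0), "> 0")
})

test_that("two-proportion sample sizes follow the selected convention", {
  expect_equal(sample_size_two_proportions(0.35, 0.05)$n_per_group, 24L)
  expect_equal(sample_size_two_proportions(0.35, 0.05, method = "arcsine")$n_per_group, 12L)
  pooled <- sample_size_two_proportions(0.35, 0.05, method = "pooled-normal")
  expect_equal(pooled$n_per_group, 27L)
  # oracle: direct evaluation of the unpooled formula
  z <- stats::qnorm(0.975) + stats::qnorm(0.80)
  expect_equal(sample_size_two_proportions(0.35, 0.05)$n_exact,
               z^2 * (0.35 * 0.65 + 0.05 * 0.95) / 0.30^2, tolerance = 1e-12)
  # larger effects need fewer subjects; higher power needs more
  expect_lt(sample_size_two_proportions(0.50, 0.05)$n_per_group, 24L)
  expect_gt(sample_size_two_proportions(0.35, 0.05, power = 0.9)$n_per_group, 24L)
  expect_error(sample_size_two_proportions(0.3, 0.3), "differ")
})

test_that("group summary tables have fixed row order and exact summaries", {
  set.seed(77)
  n <- 12
  features <- tibble::tibble(
    group_label = rep(c("a", "b"), each = n / 2),
    se = stats::rnorm(n, 40), aeeg_upper_uv = stats::rnorm(n, 14),
    aeeg_lower_uv = stats::rnorm(n, 9), rav_pct = stats::rnorm(n, 25),
    delta_pct = stats::rnorm(n, 70), theta_pct = stats::rnorm(n, 10),
    alpha_pct = stats::rnorm(n, 12), beta_pct = stats::rnorm(n, 8),
    sef95_hz = stats::rnorm(n, 10)
  )
  tab <- summarize_groups(features)
  expect_equal(tab$feature,
               c("se", "aeeg_upper_uv", "aeeg_lower_uv", "rav_pct", "delta_pct",
                 "theta_pct", "alpha_pct", "beta_pct", "sef95_hz"))
  expect_true(all(tab$test == "welch"))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  # summaries equal a brute-force mean/sd recomputation
  long <- tidy(tab)
  for (i in seq_len(nrow(long))) {
    v <- features[[long$feature[i]]][features$group_label == long$label[i]]
    expect_equal(long$mean[i], mean(v), tolerance = 1e-9)
    expect_equal(long$sd[i], stats::sd(v), tolerance = 1e-9)
    expect_equal(long$sem[i], stats::sd(v) / sqrt(length(v)), tolerance = 1e-9)
  }
  # identical groups: every p-value is 1
  dup <- features; dup$group_label <- rep(c("a", "b"), times = n / 2)
  dup[dup$group_label == "b", -1] <- dup[dup$group_label == "a", -1]
  tab2 <- summarize_groups(dup)
  expect_true(all(abs(tab2$p_value - 1) < 1e-12))
  # a singleton group is rejected (SEM undefined)
  expect_error(summarize_groups(features[c(1, 7), ]), ">= 2 subjects")
})

test_that("three or more groups switch to one-way ANOVA", {
  set.seed(5)
  features <- tibble::tibble(
    group_label = rep(c("a", "b", "c"), each = 4),
    se = stats::rnorm(12, 40), sef95_hz = stats::rnorm(12, 10)
  )
  tab <- summarize_groups(features)
  expect_true(all(tab$test == "anova"))
  expect_equal(glance(tab)$n_groups, 3)
})

test_that("published summary-table contrasts reproduce the printed significance", {
  # SEF95, cardiac vs non-cardiac: printed p = 0.0003
  r <- welch_t_from_summary(9.46, 0.75, 24, 14.31, 1.01, 22)
  expect_lt(r$p_value, 1e-3)
  expect_gt(r$p_value, 1e-5)
  expect_lt(r$statistic, 0)
})
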