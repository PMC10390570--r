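make_sample_profiles <- function(n_single, n_multiple, n_abnormal) {
  c(lapply(seq_len(n_single), function(i)
      make_profile(n_trb_f = 1, n_tra_f = 1, barcode = sprintf("S%d", i))),
    lapply(seq_len(n_multiple), function(i)
      make_profile(n_trb_f = 2, n_tra_f = 1, barcode = sprintf("M%d", i))),
    lapply(seq_len(n_abnormal), function(i)
      make_profile(n_trb_f = 1, barcode = sprintf("A%d", i))))
}

test_that("sample summaries compute the documented percentages", {
  profs <- make_sample_profiles(17, 3, 30)
  s <- summarize_sample(profs, "X")
  expect_equal(s$n_cells, 50L)
  expect_equal(s$n_functional, 20L)
  expect_equal(s$pct_functional, 100 * 20 / 50)
  expect_equal(s$pct_single, 100 * 17 / 20)
  expect_equal(s$pct_multiple, 100 * 3 / 20)
  expect_equal(s$pct_abnormal, 100 * 30 / 50)
  expect_equal(sum(s$pattern_freqs), 1)
  expect_equal(sum(s$group_freqs), 1)
  expect_equal(s$n_functional + round(s$pct_abnormal / 100 * s$n_cells),
               s$n_cells)
})

test_that("zero functional cells give undefined single/multiple splits, not 0", {
  profs <- make_sample_profiles(0, 0, 10)
  s <- summarize_sample(profs, "X")
  expect_equal(s$pct_functional, 0)
  expect_equal(s$pct_abnormal, 100)
  expect_true(is.na(s$pct_single))
  expect_true(is.na(s$pct_multiple))
})

test_that("group aggregation is an unweighted mean and permutation-invariant", {
  df <- data.frame(sample_id = c("a", "b", "c"),
                   pct_functional = c(10, 20, 60),
                   pct_single = c(90, 80, 70),
                   pct_multiple = c(10, 20, 30))
  g <- aggregate_group(df, "G")
  expect_equal(g$mean_pct_functional, 30)
  expect_equal(g$mean_pct_single, 80)
  set.seed(1)
  for (i in 1:5) {
    gp <- aggregate_group(df[sample(3), ], "G")
    expect_equal(gp$mean_pct_functional, g$mean_pct_functional)
    expect_equal(gp$mean_pct_multiple, g$mean_pct_multiple)
  }
  g1 <- aggregate_group(df[2, ], "G1")
  expect_equal(g1$mean_pct_functional, 20)
  expect_error(aggregate_group(df[0, ], "E"), "empty")
})

test_that("identical normal groups give t = 0, p = 1", {
  res <- compare_groups(list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5)))
  expect_equal(res$test_name, "t_test_two_tailed")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$significance_label, "ns")
})

test_that("three normal homoscedastic groups dispatch to one-way ANOVA", {
  vals <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(10, 11, 12))
  res <- compare_groups(vals)
  expect_equal(res$test_name, "anova_one_way")
  # textbook computation: group means 2, 3, 11; grand mean 16/3;
  # SSB = 3*((2-16/3)^2 + (3-16/3)^2 + (11-16/3)^2), SSW = 2+2+2
  ssb <- 3 * sum((c(2, 3, 11) - 16 / 3)^2)
  f_hand <- (ssb / 2) / (6 / 6)
  expect_equal(res$statistic, f_hand, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pf(f_hand, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
})

test_that("non-normal data fall through to the rank-based tests", {
  set.seed(9)
  skewed <- function(n) exp(stats::rnorm(n, 0, 2))
  two <- compare_groups(list(a = skewed(20), b = skewed(20) * 4))
  three <- compare_groups(list(a = skewed(15), b = skewed(15),
                               c = skewed(15) * 5))
  expect_true(two$test_name %in% c("mann_whitney", "t_test_two_tailed"))
  expect_true(three$test_name %in% c("kruskal_wallis", "anova_one_way"))
  # groups too small for a normality screen use the non-parametric branch
  tiny <- compare_groups(list(a = c(1, 2), b = c(5, 8)))
  expect_equal(tiny$test_name, "mann_whitney")
})

test_that("significance labels follow the two-threshold convention", {
  expect_equal(significance_label(0.004), "**")
  expect_equal(significance_label(0.03), "*")
  expect_equal(significance_label(0.2), "ns")
  expect_equal(significance_label(0.05), "ns")
  res <- compare_groups(list(a = c(1, 2, 3), b = c(101, 102, 103)))
  expect_equal(res$significance_label, "**")
})

test_that("group-label permutation yields calibrated p-values", {
  set.seed(202)
  pool <- stats::rnorm(10, 50, 5)
  ps <- replicate(200, {
    perm <- sample(pool)
    compare_groups(list(a = perm[1:5], b = perm[6:10]))$p_value
  })
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("errors are raised for degenerate group structures", {
  expect_error(compare_groups(list(a = c(1, 2))), "two groups")
  expect_error(compare_groups(list(a = c(1, 2), b = 3)), "at least two values")
})

test_that("percent formatting is 3-decimal half-up", {
  expect_equal(format_pct(10.8955), "10.896")
  expect_equal(format_pct(100 * 1668 / 5208), "32.028")
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-2.5, 0), -3)
  expect_true(is.na(format_pct(NA_real_)))
})
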