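test_that("Bland-Altman bias and limits follow the difference distribution", {
  ba <- bland_altman(c(5, 5, 5), c(5, 5, 5))
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))

  # hand-computed example: d = {-50, -10, 10}
  ba <- bland_altman(c(0, 0, 0) + c(-50, -10, 10), c(0, 0, 0))
  expect_equal(ba$bias, -50 / 3)
  expect_equal(ba$sd_diff, 30.551, tolerance = 1e-4)
  expect_equal(ba$loa_low, -76.55, tolerance = 1e-3)
  expect_equal(ba$loa_high, 43.21, tolerance = 1e-3)

  # oracle equivalence on random pairs
  set.seed(11)
  a <- rnorm(25, 300, 50)
  b <- rnorm(25, 350, 60)
  ba <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba$bias, sum(d) / 25)
  expect_equal(ba$sd_diff, sqrt(sum((d - mean(d))^2) / 24))
  expect_error(bland_altman(1:2, 3:4), "3")
})

test_that("coefficient of variation is SD over mean, scale-invariant", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50)
  set.seed(2)
  x <- rlnorm(30)
  expect_equal(coefficient_of_variation(3.7 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(5), "n >= 2")
})

test_that("Forkman's CoV-equality F statistic and symmetries", {
  eq <- forkman_cov_test(0.3, 10, 0.3, 10)
  expect_equal(eq$F, 1)
  expect_equal(eq$p, 1)

  ft <- forkman_cov_test(0.293, 19, 0.501, 19)
  expect_equal(round(ft$F, 2), 0.39)
  expect_equal(ft$df1, 18)
  expect_equal(ft$df2, 18)

  # swapping samples reciprocates F and leaves the two-sided p unchanged
  sw <- forkman_cov_test(0.501, 19, 0.293, 19)
  expect_equal(sw$F, 1 / ft$F)
  expect_equal(sw$p, ft$p, tolerance = 1e-12)

  # percent inputs are accepted
  expect_equal(forkman_cov_test(29.3, 19, 50.1, 19)$F, ft$F)
  expect_error(forkman_cov_test(-0.1, 10, 0.3, 10), "positive")
})

test_that("Welch t agrees between sample and summary paths", {
  same <- welch_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # printed-summary path: group means/SEs of liver T1
  wt <- welch_t(list(mean = 1533, se = 50, n = 9),
                list(mean = 1256, se = 18, n = 10))
  expect_equal(wt$t, 5.213, tolerance = 1e-3)
  expect_equal(wt$df, 10.06, tolerance = 1e-2)
  expect_lt(wt$p, 0.001)

  # the two paths coincide on the same data
  set.seed(5)
  x <- rnorm(12, 10, 2)
  y <- rnorm(9, 12, 4)
  ws <- welch_t(x, y)
  wm <- welch_t(list(mean = mean(x), se = sd(x) / sqrt(12), n = 12),
                list(mean = mean(y), se = sd(y) / sqrt(9), n = 9))
  expect_equal(ws$t, wm$t, tolerance = 1e-12)
  expect_equal(ws$df, wm$df, tolerance = 1e-12)
  expect_equal(ws$p, wm$p, tolerance = 1e-12)
  expect_error(welch_t(list(mean = 1, se = 0, n = 5),
                       list(mean = 2, se = 0, n = 5)), "variance")
})

test_that("Mann-Whitney exact enumeration matches reference results", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)

  tied <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied$p, 1)

  # independent oracle: stats::wilcox.test exact p for untied samples
  set.seed(9)
  for (i in 1:10) {
    x <- sample(1:100, 4)
    y <- sample(101:200, 4) - sample(1:100, 4)
    while (any(y %in% x)) y <- y + 0.5
    mw <- mann_whitney_u(x, y)
    wt <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    expect_equal(mw$p, wt$p.value, tolerance = 1e-12)
    expect_equal(mw$U, unname(wt$statistic))
  }

  # large samples switch to the tie-corrected normal approximation
  set.seed(10)
  big <- mann_whitney_u(rnorm(15), rnorm(15, 1))
  expect_equal(big$method, "normal approximation")
  expect_lt(big$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("KS normality distance matches the brute-force supremum", {
  set.seed(4)
  x <- rexp(30)
  ks <- ks_normality(x, n_mc = 500L)
  z <- sort((x - mean(x)) / sd(x))
  n <- length(z)
  brute <- max(vapply(seq_len(n), function(i) {
    max(i / n - pnorm(z[i]), pnorm(z[i]) - (i - 1) / n)
  }, numeric(1)))
  expect_equal(ks$D, brute, tolerance = 1e-12)

  # independent implementation of the same Lilliefors distance
  expect_equal(ks$D, unname(nortest::lillie.test(x)$statistic),
               tolerance = 1e-12)

  # exact normal quantiles give near-minimal D
  q <- qnorm(((1:20) - 0.5) / 20)
  expect_lt(ks_normality(q, n_mc = 500L)$D, 0.06)

  # power against a heavily skewed alternative
  set.seed(12)
  rejections <- vapply(1:20, function(i) {
    ks_normality(rexp(50), n_mc = 2000L, seed = 100 + i)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.95)
  expect_error(ks_normality(c(1, 2, 3)), "n >= 4")
})

test_that("split-plot interaction equals the change-score contrast", {
  mk <- function(groups, base, post) {
    n <- length(base)
    data.frame(subject = rep(seq_len(n), 2),
               group = rep(groups, 2),
               time = rep(c("baseline", "post"), each = n),
               value = c(base, post))
  }
  # equal mean changes in both groups: no interaction
  d <- mk(c("A", "A", "B", "B"), c(0, 5, 10, 20), c(2, 9, 11, 25))
  an <- mixed_anova_2x2(d, baseline_level = "baseline")
  expect_equal(an$F, 0)

  # worked example: changes {10,14} vs {0,2} -> F = (11/sqrt(5))^2 = 24.2
  d <- mk(c("A", "A", "B", "B"), c(0, 0, 0, 0), c(10, 14, 0, 2))
  an <- mixed_anova_2x2(d, baseline_level = "baseline")
  expect_equal(an$F, 24.2, tolerance = 1e-10)
  expect_equal(c(an$df1, an$df2), c(1, 2))
  expect_equal(an$posthoc$p_adj, pmin(1, 2 * an$posthoc$p_raw))

  # adding per-subject constants to both time points leaves F unchanged
  d2 <- d
  offs <- c(100, -20, 7, 55)
  d2$value <- d2$value + offs[d2$subject]
  expect_equal(mixed_anova_2x2(d2, baseline_level = "baseline")$F, an$F)

  # subjects missing a time point are dropped with a warning
  d3 <- mk(c("A", "A", "A", "B", "B"), c(0, 0, 0, 0, 0), c(10, 14, 12, 0, 2))
  d3 <- d3[!(d3$subject == 3 & d3$time == "post"), ]
  expect_warning(an3 <- mixed_anova_2x2(d3, baseline_level = "baseline"),
                 "dropping")
  expect_equal(an3$n_subjects, 4L)
})

test_that("attrition inflation rounds the required size upward", {
  expect_equal(attrition_inflate(6, 0.30), 9L)
  expect_equal(attrition_inflate(6, 0), 6L)
  expect_equal(attrition_inflate(10, 0.5), 20L)
  expect_error(attrition_inflate(6, 1), "attrition_rate")
})
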