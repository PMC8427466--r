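# Statistical layer: method agreement, variability comparison, group
# comparisons and the split-plot response analysis. Standard machinery
# (t tests, F distributions, linear models) is delegated to stats::;
# the agreement/CoV-equality procedures are implemented directly.

#' Bland-Altman agreement analysis
#'
#' Differences d = a - b between two methods measured on the same
#' subjects; bias = mean(d), 95% limits of agreement = bias +/- 1.96 x
#' sample SD of d (the conventional normal-quantile multiplier, not the
#' small-sample t quantile).
#'
#' @param a,b paired measurements from the two methods, equal length >= 3.
#' @return list of class `agreement_result`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, `se_bias`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired", call. = FALSE)
  d <- a - b
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3L) stop("at least 3 complete pairs are required", call. = FALSE)
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 se_bias = sd_diff / sqrt(n), n = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n=%d): bias %.2f +/- %.2f (SE), 95%% LoA [%.2f, %.2f]\n",
              x$n, x$bias, x$se_bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Coefficient of variation
#'
#' 100 x sample SD (n-1 denominator) / mean. Scale-invariant for positive
#' scalings.
#'
#' @param x numeric sample, n >= 2, non-zero mean.
#' @return CoV, percent.
#' @export
coefficient_of_variation <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("n >= 2 required", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("CoV undefined for zero mean", call. = FALSE)
  100 * stats::sd(x) / m
}

#' Forkman's F test for equality of two coefficients of variation
#'
#' Tests whether two independent normal samples share a common CoV using
#' the statistic
#' `F = [c1^2 / (1 + c1^2 (n1-1)/n1)] / [c2^2 / (1 + c2^2 (n2-1)/n2)]`
#' referred to an F(n1 - 1, n2 - 1) distribution. Two-sided p =
#' `2 min(P(F <= f), P(F >= f))`; the one-sided lower tail is also
#' returned. Swapping the samples maps F to 1/F and leaves the two-sided p
#' unchanged.
#'
#' @param cov1,cov2 sample CoVs as fractions (0.293 for 29.3%); values
#'   above 1.5 are interpreted as percent and divided by 100.
#' @param n1,n2 sample sizes (>= 2).
#' @return list of class `cov_test_result`: `cov1`, `cov2` (percent), `F`,
#'   `df1`, `df2`, `p` (two-sided), `p_one_sided`.
#' @references Forkman J (2009). Estimator and tests for common
#'   coefficients of variation in normal distributions. Communications in
#'   Statistics - Theory and Methods 38(2):233-251.
#' @export
forkman_cov_test <- function(cov1, n1, cov2, n2) {
  if (cov1 <= 0 || cov2 <= 0) stop("CoVs must be positive", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("sample sizes must be >= 2", call. = FALSE)
  if (cov1 > 1.5) cov1 <- cov1 / 100
  if (cov2 > 1.5) cov2 <- cov2 / 100
  adj <- function(c, n) c^2 / (1 + c^2 * (n - 1) / n)
  f <- adj(cov1, n1) / adj(cov2, n2)
  df1 <- n1 - 1
  df2 <- n2 - 1
  lower <- stats::pf(f, df1, df2)
  structure(list(cov1 = 100 * cov1, cov2 = 100 * cov2, F = f,
                 df1 = df1, df2 = df2,
                 p = min(1, 2 * min(lower, 1 - lower)),
                 p_one_sided = min(lower, 1 - lower)),
            class = "cov_test_result")
}

#' @export
print.cov_test_result <- function(x, ...) {
  cat(sprintf("Forkman CoV test: %.1f%% vs %.1f%%, F[%d, %d] = %.3f, p = %.4f\n",
              x$cov1, x$cov2, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Forkman's test from two raw samples
#'
#' @param x,y numeric samples.
#' @return as [forkman_cov_test()].
#' @export
forkman_cov_test_samples <- function(x, y) {
  forkman_cov_test(coefficient_of_variation(x) / 100, length(x),
                   coefficient_of_variation(y) / 100, length(y))
}

#' Welch's unequal-variance t test
#'
#' Unpaired two-group comparison with Welch's correction for unequal
#' standard deviations. Accepts either raw samples (delegated to
#' [stats::t.test()]) or printed group summaries as
#' `list(mean =, se =, n =)` -- published tables report means and standard
#' errors, so the summary path works from SEs directly:
#' `t = (m1 - m2) / sqrt(se1^2 + se2^2)` with Welch-Satterthwaite degrees
#' of freedom.
#'
#' @param g1,g2 numeric vectors, or summary lists with `mean`, `se`, `n`.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(g1, g2) {
  as_summary <- function(g) {
    if (is.list(g)) {
      stopifnot(all(c("mean", "se", "n") %in% names(g)))
      if (g$n < 2) stop("n >= 2 required", call. = FALSE)
      g
    } else {
      if (length(g) < 2) stop("n >= 2 required", call. = FALSE)
      list(mean = mean(g), se = stats::sd(g) / sqrt(length(g)), n = length(g))
    }
  }
  if (!is.list(g1) && !is.list(g2)) {
    ht <- stats::t.test(g1, g2, var.equal = FALSE)
    return(list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value))
  }
  s1 <- as_summary(g1)
  s2 <- as_summary(g2)
  v1 <- s1$se^2
  v2 <- s2$se^2
  if (v1 + v2 == 0) stop("zero variance in both groups", call. = FALSE)
  t <- (s1$mean - s2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (s1$n - 1) + v2^2 / (s2$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. For n1 + n2 <= 20 the
#' two-sided p-value is computed by exact enumeration of all group
#' assignments (valid under ties); larger samples use the normal
#' approximation with tie correction. U counts pairs where the first
#' sample exceeds the second (ties count 1/2); the two-sided p is the
#' probability of a U at least as far from n1 n2 / 2 as observed.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  rk <- rank(pooled)
  r1 <- sum(rk[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2          # pairs x > y (+1/2 per tie)
  centre <- n1 * n2 / 2

  if (n1 + n2 <= 20) {
    combos <- utils::combn(n1 + n2, n1)
    rks <- matrix(rk[combos], nrow = n1)
    us <- colSums(rks) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - centre) >= abs(u - centre) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    z <- (abs(u - centre) - 0.5) / sigma   # continuity-corrected
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  list(U = u, p = p, method = method)
}

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' D = sup |empirical CDF - fitted normal CDF| with mean and SD estimated
#' from the sample. Because the parameters are estimated, the classical KS
#' null is wrong (anti-conservative D distribution); the p-value is
#' obtained from the Lilliefors-corrected null by seeded Monte-Carlo
#' simulation (default 10^4 replicates).
#'
#' @param x numeric sample, n >= 4.
#' @param n_mc Monte-Carlo replicates for the null distribution.
#' @param seed RNG seed for the null simulation.
#' @return list with `D`, `p`, `n`.
#' @export
ks_normality <- function(x, n_mc = 10000L, seed = 171L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) stop("n >= 4 required", call. = FALSE)
  D_of <- function(z) {
    # z: sorted standardised sample
    p <- stats::pnorm(z)
    i <- seq_len(length(z))
    max(i / length(z) - p, p - (i - 1) / length(z))
  }
  std <- function(v) (sort(v) - mean(v)) / stats::sd(v)
  d <- D_of(std(x))
  d_null <- with_seed(seed, {
    sims <- matrix(stats::rnorm(n * n_mc), n, n_mc)
    apply(sims, 2, function(v) D_of(std(v)))
  })
  p <- (1 + sum(d_null >= d)) / (n_mc + 1)
  list(D = d, p = p, n = n)
}

#' Split-plot (mixed-model) two-way ANOVA for a 2 x 2 design
#'
#' One between-subject factor (group) by one within-subject factor (time,
#' two levels, both measured on every subject). For this design the
#' group x time interaction is exactly the between-group comparison of
#' per-subject change scores: the interaction F with df (1, n_subjects - 2)
#' equals the squared pooled-variance two-sample t on the changes, which
#' handles unbalanced groups without choosing a sums-of-squares type.
#' Subjects missing a time point are dropped with a warning (mirroring
#' attrition). Post hoc per-group paired t tests are Bonferroni-adjusted
#' for the two comparisons.
#'
#' @param data data.frame with columns `subject`, `group` (2 levels),
#'   `time` (2 levels), `value`.
#' @param baseline_level which level of `time` is the baseline; defaults to
#'   the first factor level.
#' @return list of class `anova_result`: `F`, `df1`, `df2`, `p`,
#'   `posthoc` (data.frame: group, mean_change, se_change, t, df, p_raw,
#'   p_adj), `n_subjects`.
#' @export
mixed_anova_2x2 <- function(data, baseline_level = NULL) {
  stopifnot(all(c("subject", "group", "time", "value") %in% names(data)))
  data$group <- factor(data$group)
  data$time <- factor(data$time)
  if (nlevels(data$group) != 2L || nlevels(data$time) != 2L) {
    stop("group and time must each have exactly 2 levels", call. = FALSE)
  }
  if (is.null(baseline_level)) baseline_level <- levels(data$time)[1]
  post_level <- setdiff(levels(data$time), baseline_level)

  wide <- stats::reshape(
    data[, c("subject", "group", "time", "value")],
    idvar = c("subject", "group"), timevar = "time", direction = "wide")
  b_col <- paste0("value.", baseline_level)
  p_col <- paste0("value.", post_level)
  complete <- stats::complete.cases(wide[, c(b_col, p_col)])
  if (any(!complete)) {
    warning(sprintf("dropping %d subject(s) missing a time point: %s",
                    sum(!complete),
                    paste(wide$subject[!complete], collapse = ", ")),
            call. = FALSE)
    wide <- wide[complete, ]
  }
  if (any(table(wide$group) < 2)) {
    stop("at least 2 complete subjects per group are required", call. = FALSE)
  }
  wide$change <- wide[[p_col]] - wide[[b_col]]

  fit <- stats::lm(change ~ group, data = wide)
  an <- stats::anova(fit)
  f <- an[["F value"]][1]
  df2 <- an[["Df"]][2]

  posthoc <- do.call(rbind, lapply(levels(wide$group), function(g) {
    ch <- wide$change[wide$group == g]
    # paired baseline-vs-post comparison == one-sample t on the changes;
    # zero-variance changes are degenerate (p = 1 if no change, else ~0)
    ht <- tryCatch(stats::t.test(ch), error = function(e) NULL)
    if (is.null(ht)) {
      p_raw <- if (all(ch == 0)) 1 else 0
      ht <- list(statistic = c(t = if (all(ch == 0)) 0 else Inf),
                 parameter = c(df = length(ch) - 1), p.value = p_raw)
    }
    data.frame(group = g, mean_change = mean(ch),
               se_change = stats::sd(ch) / sqrt(length(ch)),
               t = unname(ht$statistic), df = unname(ht$parameter),
               p_raw = ht$p.value, p_adj = min(1, 2 * ht$p.value))
  }))
  structure(list(F = f, df1 = 1L, df2 = df2, p = an[["Pr(>F)"]][1],
                 posthoc = posthoc, n_subjects = nrow(wide)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Group x time interaction: F[%d, %d] = %.3f, p = %.4f (n = %d)\n",
              x$df1, x$df2, x$F, x$p, x$n_subjects))
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Attrition-adjusted sample size
#'
#' Inflates a required sample size to allow for expected attrition:
#' `ceiling(n_required / (1 - rate))`.
#'
#' @param n_required subjects needed at analysis.
#' @param attrition_rate expected attrition fraction in [0, 1).
#' @return integer projected recruitment size.
#' @export
attrition_inflate <- function(n_required, attrition_rate) {
  if (n_required < 1) stop("n_required must be >= 1", call. = FALSE)
  if (attrition_rate < 0 || attrition_rate >= 1) {
    stop("attrition_rate must lie in [0, 1)", call. = FALSE)
  }
  as.integer(ceiling(n_required / (1 - attrition_rate)))
}
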