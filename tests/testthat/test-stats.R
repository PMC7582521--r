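# cohort statistics: Spearman, group comparisons, adjusted regression,
# descriptives, timecourse comparisons

test_that("Spearman correlation handles monotone data and midrank ties", {
  x <- c(1, 2, 3, 5, 8, 13, 21)
  expect_equal(spearman_cor(x, exp(x))$rs, 1)
  expect_equal(spearman_cor(x, -x^3)$rs, -1)
  # 8-point vectors with ties against the hand midrank formula
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5)
  yt <- c(2, 1, 4, 4, 3, 7, 6, 6)
  r <- spearman_cor(xt, yt)
  expect_equal(r$rs, oracle_spearman(xt, yt), tolerance = 1e-12)
  # agrees with the reference implementation, including the t-based p
  ref <- suppressWarnings(cor.test(xt, yt, method = "spearman"))
  expect_equal(r$rs, unname(ref$estimate), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman_cor(exp(a), b)$rs, spearman_cor(a, b)$rs)
  expect_equal(spearman_cor(a, qlogis(plogis(b)))$rs, spearman_cor(a, b)$rs)
  # degenerate input
  expect_true("zero_variance" %in% spearman_cor(rep(1, 6), 1:6)$flags)
  expect_error(spearman_cor(1:3, 1:3), "4 complete")
})

test_that("adjusted group effect solves the normal equations", {
  # outcome identical to fibrinogen: zero group effect, unit slope
  tab <- data.frame(group = factor(rep(c("control", "DM"), 8),
                                   levels = c("control", "DM")),
                    fibrinogen = seq(2, 5, length.out = 16))
  tab$y <- tab$fibrinogen
  r <- adjusted_group_effect(tab, "y")
  expect_lt(abs(r$adjusted$B), 1e-8)
  expect_equal(unname(r$adjusted$coefs["fibrinogen"]), 1, tolerance = 1e-8)
  # 12-row hand table against closed-form OLS
  set.seed(8)
  h <- data.frame(group = factor(rep(c("control", "DM"), each = 6),
                                 levels = c("control", "DM")),
                  fibrinogen = c(3.1, 2.8, 3.5, 4.0, 3.3, 2.9,
                                 4.1, 3.6, 3.9, 4.4, 3.2, 3.8))
  h$y <- c(55, 60, 62, 71, 64, 57, 70, 66, 73, 80, 61, 69)
  rh <- adjusted_group_effect(h, "y")
  X <- cbind(1, as.numeric(h$group == "DM"), h$fibrinogen)
  beta <- oracle_ols_coefs(X, h$y)
  expect_equal(unname(rh$adjusted$coefs), beta, tolerance = 1e-10)
  Xu <- X[, 1:2]
  expect_equal(unname(rh$unadjusted$coefs), oracle_ols_coefs(Xu, h$y),
               tolerance = 1e-10)
  # adjusted equals unadjusted when fibrinogen is constant... which is
  # reported as an error naming the offending column
  hc <- h; hc$fibrinogen <- 3.5
  expect_error(adjusted_group_effect(hc, "y"), "fibrinogen")
  expect_error(adjusted_group_effect(h, "nope"), "no such outcome")
})

test_that("simulated cohorts recover the injected DM effect", {
  B <- vapply(1:100, function(s) {
    tab <- simulate_cohort(seed = 20000 + s)
    adjusted_group_effect(tab, "fiber_diameter_nm")$adjusted$B
  }, numeric(1))
  expect_lt(abs(mean(B) - 6.70) / 6.70, 0.15)  # tight check in acceptance
})

test_that("log-transformed outcomes are modeled on the log scale", {
  set.seed(5)
  tab <- data.frame(group = factor(rep(c("control", "DM"), each = 10),
                                   levels = c("control", "DM")),
                    fibrinogen = rnorm(20, 3.5, 0.5))
  tab$k <- exp(1 + 0.5 * (tab$group == "DM") + rnorm(20, 0, 0.1))
  r <- adjusted_group_effect(tab, "k", log_transform = TRUE)
  expect_lt(abs(r$adjusted$B - 0.5), 0.25)
  tab$k[1] <- -1
  expect_error(adjusted_group_effect(tab, "k", log_transform = TRUE),
               "non-positive")
})

test_that("group comparison selects the test and mirrors table formats", {
  set.seed(4)
  x <- rnorm(12, 10, 1)
  same <- group_compare(x, x)
  expect_equal(same$effect, 0)
  expect_gte(same$p, 0.99)
  # clearly non-normal data routes to Mann-Whitney
  skew <- exp(rnorm(40, 0, 1.5))
  g <- group_compare(skew, skew * 1.1)
  expect_equal(g$method_used, "mannwhitney")
  expect_match(g$summary_dm, "\\[")
  # forced t on normal data reports mean +/- sd
  gt <- group_compare(rnorm(15, 5), rnorm(15, 5), method = "t")
  expect_match(gt$summary_dm, "±")
  # a 2-sd shift is essentially always detected
  hits <- vapply(1:100, function(s) {
    set.seed(30000 + s)
    group_compare(rnorm(20, 2, 1), rnorm(26, 0, 1))$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.99)
  expect_error(group_compare(1:2, 1:5), "at least 3")
  const <- group_compare(rep(1, 5), rep(1, 5))
  expect_true("constant_data" %in% const$flags)
})

test_that("timecourse comparison is per-timepoint with Bonferroni", {
  t <- seq(0, 180, 15)
  set.seed(6)
  mk <- function(shift_at_90 = 0) {
    lapply(1:10, function(i) {
      y <- 100 + 10 * t + rnorm(length(t), 0, 20)
      y[t == 90] <- y[t == 90] + shift_at_90
      lysis_series(t, pmax(y, 0))
    })
  }
  # identical group means: all adjusted p near 1
  a <- mk(); b <- mk()
  res <- timecourse_compare(a, b)
  expect_equal(nrow(res), length(t))
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj <= 1))
  # single timepoint: Bonferroni identity
  one <- timecourse_compare(matrix(rnorm(10), 1), matrix(rnorm(10), 1),
                            time = 0)
  expect_equal(one$p_adj, min(1, one$p))
  # mismatched grids are rejected
  short <- lapply(a, function(s) lysis_series(t[-1], s$fluorescence[-1]))
  expect_error(timecourse_compare(a, short), "grid")
})

test_that("divergence at one timepoint is localized by the comparison", {
  t <- seq(0, 180, 15)
  hits <- 0L; leaks <- 0L; nsim <- 100
  for (s in 1:nsim) {
    set.seed(40000 + s)
    m_dm <- vapply(1:10, function(i) rnorm(length(t), 100, 20),
                   numeric(length(t)))
    m_ct <- vapply(1:10, function(i) rnorm(length(t), 100, 20),
                   numeric(length(t)))
    m_dm[t == 90, ] <- m_dm[t == 90, ] + 2.5 * 20
    res <- timecourse_compare(m_dm, m_ct, time = t)
    if (res$p_adj[t == 90] < 0.05) hits <- hits + 1L
    if (any(res$p_adj[t != 90] < 0.05)) leaks <- leaks + 1L
  }
  expect_gte(hits / nsim, 0.9)
  expect_lt(leaks / nsim, 0.2)
})

test_that("descriptives reproduce count percentages and group tests", {
  # printed-count check: 31 statin users of 46 is 67%
  tab <- data.frame(group = factor(rep(c("DM", "control"), c(20, 26)),
                                   levels = c("control", "DM")),
                    statins = rep(c("yes", "no", "yes", "no"),
                                  c(17, 3, 14, 12)))
  d <- cohort_descriptives(tab)
  yes_row <- d[d$variable == "statins" & d$level == "yes", ]
  expect_equal(yes_row$summary_total, "31 (67%)")
  expect_equal(yes_row$summary_g2, "17 (85%)")
  expect_equal(yes_row$summary_g1, "14 (54%)")
  # chi-square equals the hand formula on the 2x2 counts
  counts <- matrix(c(17, 3, 14, 12), 2)
  e <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  x2 <- sum((counts - e)^2 / e)
  p_hand <- pchisq(x2, df = 1, lower.tail = FALSE)
  expect_equal(yes_row$p, p_hand, tolerance = 1e-12)
  # numeric variable summarized per group
  set.seed(7)
  tab$fib <- rnorm(46, 3.5, 0.7)
  d2 <- cohort_descriptives(tab, variables = "fib")
  expect_true(d2$test %in% c("t", "mannwhitney"))
  # single-group table: comparison columns flagged absent
  solo <- cohort_descriptives(tab[tab$group == "DM", ], variables = "fib")
  expect_equal(solo$test, "absent")
  expect_true(is.na(solo$p))
})
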