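test_that("subject_slope is the OLS slope with the expected invariances", {
  expect_equal(subject_slope(c(2, 4, 6, 8, 10), rep(5, 5)), 0)
  expect_equal(subject_slope(c(2, 4), c(1, 3)), 1)
  expect_equal(subject_slope(c(2, 4, 6), c(1, 2, 4)), 0.75) # by hand: 6/8
  expect_error(subject_slope(c(3, 3), c(1, 2)), "fewer than two distinct")
  expect_error(subject_slope(1:3, 1:2), "equal length")

  set.seed(1)
  for (i in 1:20) {
    t <- sort(runif(5, 0, 10)); y <- rnorm(5)
    s <- subject_slope(t, y)
    o <- sample(5)
    expect_equal(subject_slope(t[o], y[o]), s)          # order invariance
    expect_equal(subject_slope(t, y + 3.7), s)          # shift invariance
    expect_equal(subject_slope(t, 2.5 * y), 2.5 * s)    # linear scaling
  }
})

test_that("subject_mean and summarize_subjects summarise every subject", {
  expect_equal(subject_mean(c(5, 5, 5)), 5)
  expect_equal(subject_mean(c(1, 2, 3, 4)), 2.5)
  expect_equal(subject_mean(7.2), 7.2)
  expect_error(subject_mean(numeric(0)), "no responses")

  ds <- ds_linear(intercepts = rep(2, 4), slopes = rep(0.5, 4),
                  groups = c("a", "a", "b", "b"))
  s <- summarize_subjects(ds)
  expect_equal(nrow(s), 4)
  expect_equal(s$slope, rep(0.5, 4))   # exact on noise-free lines

  one <- rm_data(c("s1", "s1", "s2"), "a", c(1, 2, 1), c(0, 1, 5))
  expect_warning(s2 <- summarize_subjects(one), "undefined slope")
  expect_false(s2$slope_defined[s2$subject == "s2"])
  expect_equal(s2$mean[s2$subject == "s2"], 5)
})

test_that("the SMA time test is the one-sample t on pooled slopes", {
  summ <- function(slopes) data.frame(subject = seq_along(slopes), group = "a",
                                      slope = slopes, mean = 0,
                                      n_points = 3, slope_defined = TRUE)
  r <- sma_time_test(summ(c(-1, 1)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  expect_error(sma_time_test(summ(c(1, 1, 1))), "zero variance")

  sl <- c(0.2, 0.4, 0.1, 0.3)
  r2 <- sma_time_test(summ(sl))
  t_hand <- mean(sl) / (sd(sl) / 2)
  expect_equal(r2$statistic, t_hand)
  expect_equal(r2$df_num, 3)
  expect_equal(r2$p_value, 2 * pt(-abs(t_hand), 3))
})

test_that("SMA interaction and group tests match hand-computed k-sample tests", {
  summ2 <- function(g1, g2, what = "slope") {
    n <- length(g1) + length(g2)
    out <- data.frame(subject = seq_len(n),
                      group = rep(c("g1", "g2"), c(length(g1), length(g2))),
                      slope = 0, mean = 0, n_points = 3, slope_defined = TRUE)
    out[[what]] <- c(g1, g2)
    out
  }
  # identical slope multisets -> t = 0, p = 1
  r0 <- sma_interaction_test(summ2(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # pooled two-sample t by hand: sp2 = 1, t = -1 / sqrt(2/3)
  r <- sma_interaction_test(summ2(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(r$statistic, -1 / sqrt(2 / 3))
  expect_equal(r$df_num, 4)

  # group test on means, same machinery
  rg <- sma_group_test(summ2(c(10, 11, 12), c(13, 14, 15), what = "mean"))
  expect_equal(rg$statistic, -3 / sqrt(2 / 3))

  # three-group ANOVA against the between/within mean-square decomposition
  v <- c(1.2, 0.8, 1.1, 2.0, 2.3, 1.9, 3.2, 2.9, 3.0)
  g <- rep(c("a", "b", "c"), each = 3)
  s3 <- data.frame(subject = 1:9, group = g, slope = 0, mean = v,
                   n_points = 3, slope_defined = TRUE)
  ra <- sma_group_test(s3, variant = "anova")
  gm <- tapply(v, g, mean)
  msb <- sum(3 * (gm - mean(v))^2) / 2
  msw <- sum((v - gm[g])^2) / 6
  expect_equal(ra$statistic, msb / msw)
  expect_equal(ra$p_value, pf(msb / msw, 2, 6, lower.tail = FALSE))

  # rank-based variants run and agree with the base implementations
  rw <- sma_interaction_test(summ2(c(1, 2, 3), c(2, 3, 4)),
                             variant = "wilcoxon")
  expect_equal(rw$p_value,
               wilcox.test(c(1, 2, 3), c(2, 3, 4), exact = FALSE,
                           correct = FALSE)$p.value)
  rk <- sma_group_test(s3, variant = "kruskal")
  expect_equal(rk$p_value, kruskal.test(v, factor(g))$p.value)

  # error classes
  expect_error(sma_interaction_test(
    data.frame(subject = 1:3, group = "a", slope = 1:3, mean = 0,
               n_points = 3, slope_defined = TRUE)), "two groups")
  expect_error(sma_interaction_test(summ2(c(1, 1), c(1, 1))),
               "zero pooled variance")
})

test_that("for two groups the ANOVA F equals the squared t with identical p", {
  set.seed(4)
  for (i in 1:10) {
    s <- data.frame(subject = 1:12, group = rep(c("a", "b"), each = 6),
                    slope = rnorm(12), mean = rnorm(12), n_points = 4,
                    slope_defined = TRUE)
    rt <- sma_interaction_test(s, variant = "t")
    rf <- sma_interaction_test(s, variant = "anova")
    expect_equal(rf$statistic, rt$statistic^2, tolerance = 1e-12)
    expect_equal(rf$p_value, rt$p_value, tolerance = 1e-12)
  }
})

test_that("sampled permutation p-values are seeded, bounded and reproducible", {
  set.seed(8)
  s <- data.frame(subject = 1:16, group = rep(c("a", "b"), each = 8),
                  slope = rnorm(16, rep(c(0, 0.4), each = 8)), mean = 0,
                  n_points = 3, slope_defined = TRUE)
  r1 <- sma_interaction_test(s, variant = "permutation", perm_reps = 499,
                             seed = 7)
  r2 <- sma_interaction_test(s, variant = "permutation", perm_reps = 499,
                             seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 500)
  expect_lte(r1$p_value, 1)
})
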