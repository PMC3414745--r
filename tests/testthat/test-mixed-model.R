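test_that("lmm_design lays out the group*time fixed and random matrices", {
  ds <- ds_linear(intercepts = c(2, 2, 2, 2), slopes = c(.5, .5, .6, .6),
                  groups = c("a", "a", "b", "b"), times = c(2, 4, 6, 8, 10))
  dmat <- lmm_design(ds)
  X <- dmat[[1]]$X
  expect_equal(dim(X), c(5, 4))
  expect_equal(colnames(X), c("(Intercept)", "groupb", "time",
                              "groupb:time"))
  # reference-group subject: group and interaction columns all zero
  expect_equal(unname(X[, "groupb"]), rep(0, 5))
  expect_equal(unname(X[, "groupb:time"]), rep(0, 5))
  # non-reference subject: interaction column equals time
  X2 <- dmat[[3]]$X
  expect_equal(unname(X2[, "groupb:time"]), c(2, 4, 6, 8, 10))
  expect_equal(dim(dmat[[1]]$Z), c(5, 1))
  Z2 <- lmm_design(ds, random = "intercept-slope")[[1]]$Z
  expect_equal(dim(Z2), c(5, 2))
  expect_equal(unname(Z2[, 2]), c(2, 4, 6, 8, 10))
  # configurable reference level
  Xr <- lmm_design(ds, ref_level = "b")[[1]]$X
  expect_equal(colnames(Xr)[2], "groupa")
})

test_that("REML variance components equal the ANOVA moment estimators on balanced IND data", {
  set.seed(31)
  n <- 30; m <- 6; tj <- 2 * (1:m)
  b0 <- rnorm(n, 0, 0.6)
  y <- 2 + 0.1 * rep(tj, n) + rep(b0, each = m) + rnorm(n * m, 0, 0.7)
  ds <- rm_data(rep(1:n, each = m), "a", rep(tj, n), y)
  f <- lmm_fit(ds, random = "intercept", structure = "ind")
  expect_true(f$converged)

  # independent oracle: split the balanced data into between/within strata
  tc <- rep(tj - mean(tj), n)
  yc <- y - rep(tapply(y, rep(1:n, each = m), mean), each = m)
  slope <- sum(tc * yc) / sum(tc^2)
  sse_w <- sum((yc - slope * tc)^2)
  sigma2_hat <- sse_w / (n * (m - 1) - 1)
  ybar <- tapply(y, rep(1:n, each = m), mean)
  ms_b <- sum((ybar - mean(ybar))^2) / (n - 1)
  sigb2_hat <- ms_b - sigma2_hat / m
  expect_equal(f$vc$sigma^2, sigma2_hat, tolerance = 1e-5)
  expect_equal(f$vc$G[1, 1], sigb2_hat, tolerance = 1e-4)
})

test_that("AR1 working structure nests IND: REML log-likelihood never decreases", {
  for (s in c(101, 202)) {
    cfg <- sim_config(5, 12, structure = "ar1")
    ds <- simulate_trend_data(cfg, 1, s)
    f_ind <- lmm_fit(ds, structure = "ind")
    f_ar1 <- lmm_fit(ds, structure = "ar1")
    expect_true(f_ind$converged && f_ar1$converged)
    expect_gte(f_ar1$reml_loglik, f_ind$reml_loglik - 1e-6)
  }
})

test_that("F tests use inner-outer df, equal squared Wald t, and respect symmetry", {
  cfg <- sim_config(4, 15, beta = c(2, 0.3, 0.05, 0.02))
  ds <- simulate_trend_data(cfg, 1, 77)
  f <- lmm_fit(ds, structure = "ind")
  N <- 30; n_obs <- 120
  expect_equal(f$f_tests$group$df_den, N - 2)
  expect_equal(f$f_tests$time$df_den, n_obs - N - 2)
  expect_equal(f$f_tests$interaction$df_den, n_obs - N - 2)
  tt <- summary(f$fit)$tTable
  expect_equal(f$f_tests$group$statistic, unname(tt["group1", "t-value"]^2),
               tolerance = 1e-8)
  expect_equal(f$f_tests$interaction$statistic,
               unname(tt["group1:time", "t-value"]^2), tolerance = 1e-8)

  # duplicate the group-0 subjects as group 1: group and interaction vanish
  half <- ds[ds$group == "0", ]
  dup <- rm_data(c(half$subject, paste0("d", half$subject)),
                 rep(c("0", "1"), each = nrow(half)),
                 rep(half$time, 2), rep(half$response, 2))
  fd <- lmm_fit(dup, structure = "ind")
  expect_equal(unname(fd$beta["group1"]), 0, tolerance = 1e-8)
  expect_equal(fd$f_tests$group$statistic, 0, tolerance = 1e-10)
  expect_equal(fd$f_tests$group$p_value, 1, tolerance = 1e-8)
  expect_equal(fd$f_tests$interaction$p_value, 1, tolerance = 1e-8)
})

test_that("information criteria follow the REML logLik and parameter count", {
  cfg <- sim_config(4, 12)
  ds <- simulate_trend_data(cfg, 1, 55)
  f1 <- lmm_fit(ds, structure = "ind")        # d = 4 fixed + sigma + G11
  f2 <- lmm_fit(ds, structure = "ar1")
  expect_equal(f1$d, 6)
  expect_equal(f2$d, 7)
  expect_equal(f1$aic, -2 * f1$reml_loglik + 2 * f1$d)
  expect_equal(f1$bic, -2 * f1$reml_loglik + f1$d * log(f1$n_obs))
  expect_equal(f1$aic - f1$bic, 2 * f1$d - f1$d * log(f1$n_obs))
  # nesting: the richer model never has larger -2 logLik
  expect_lte(-2 * f2$reml_loglik, -2 * f1$reml_loglik + 1e-6)
  expect_equal(unname(lmm_criteria(f1)), c(f1$aic, f1$bic))
})

test_that("the six-model menu records infeasible fits and ranks by criterion", {
  cfg <- sim_config(4, 15)
  ds <- simulate_trend_data(cfg, 1, 9)
  menu <- lmm_menu(ds)
  expect_lte(nrow(menu$table), 6)
  ok <- menu$table$status == "ok"
  expect_true(any(ok))
  expect_equal(menu$table$AIC[menu$best["aic"]],
               min(menu$table$AIC[ok]))

  # random-intercept IND truth: that model wins BIC on sizeable data
  big <- simulate_trend_data(sim_config(5, 60), 1, 13)
  mb <- lmm_menu(big)
  best <- mb$table[mb$best["bic"], ]
  expect_equal(best$structure, "IND")
  expect_equal(best$random, "intercept")

  # m larger than the complete-subject count: UNS flagged, not fatal
  wide_m <- 10
  few <- simulate_trend_data(sim_config(wide_m, 4), 1, 3)
  mf <- lmm_menu(few)
  uns_rows <- mf$table[mf$table$structure == "UNS", ]
  expect_true(all(uns_rows$status != "ok"))
})

test_that("an infeasible unstructured request errors with parameter counts", {
  ds <- simulate_trend_data(sim_config(10, 4), 1, 3)
  expect_error(lmm_fit(ds, structure = "uns"), "infeasible")
  # off-grid subject also rejected
  off <- ds
  off$time[1] <- 3.14159
  off <- rm_data(off$subject, off$group, off$time, off$response)
  expect_error(lmm_fit(off, structure = "uns"), "infeasible")
})
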