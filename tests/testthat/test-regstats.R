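test_that("sample-size formula reproduces the planning arithmetic", {
  expect_identical(sample_size(0.5, 1.96, 0.05), 384L)
  expect_identical(sample_size(0.5, 1.96, 0.10), 96L)
  expect_identical(sample_size(0, 1.96, 0.05), 0L)
  expect_error(sample_size(0.5, 1.96, 0), "d")
  expect_error(sample_size(1.2, 1.96, 0.05), "P")
})

test_that("pearson screening selects, rejects and reports undefined candidates", {
  set.seed(10)
  n <- 200
  x <- rnorm(n)
  y <- x + rnorm(n, sd = 1.02)  # population r ~ 0.7
  d <- data.frame(target = y, good = x, self = y, flat = rep(3, n),
                  junk = rnorm(n))
  res <- pearson_select(d, "target")
  expect_equal(res$r[res$predictor == "self"], 1, tolerance = 1e-12)
  expect_equal(res$status[res$predictor == "self"], "selected")
  expect_equal(res$status[res$predictor == "flat"], "undefined")
  expect_equal(res$status[res$predictor == "good"], "selected")
  # independent recomputation via the covariance formula
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r[res$predictor == "good"], r_direct, tolerance = 1e-12)
  expect_lt(abs(res$r[res$predictor == "good"] - 0.7), 0.1)
  expect_error(pearson_select(d, "absent"), "target")
})

test_that("fit_mlr interpolates exact linear data and matches single-predictor r^2", {
  x <- data.frame(x = 1:20)
  f <- fit_mlr(x, 2 + 3 * x$x)
  expect_equal(f$model$intercept, 2, tolerance = 1e-9)
  expect_equal(unname(f$model$coefficients["x"]), 3, tolerance = 1e-9)
  expect_equal(f$summary$r_square, 1, tolerance = 1e-12)
  set.seed(4)
  x2 <- data.frame(v = rnorm(60))
  y2 <- 1 + 0.8 * x2$v + rnorm(60, sd = 0.7)
  f2 <- fit_mlr(x2, y2)
  expect_equal(f2$summary$r_square, cor(x2$v, y2)^2, tolerance = 1e-12)
})

test_that("fit_mlr recovers the image-model coefficients from simulated cohorts", {
  set.seed(2026)
  truth <- c(-780.532, 7.269, -5.031, 16.781, 102.989)
  X <- data.frame(ac_cm = rnorm(384, 33, 3), bpd_cm = rnorm(384, 9, 0.8),
                  fl_cm = rnorm(384, 7, 0.7), ga_weeks = rnorm(384, 35.26, 3.04))
  y <- truth[1] + as.matrix(X) %*% truth[-1] + rnorm(384, sd = 349)
  f <- fit_mlr(X, as.numeric(y))
  dev <- abs(f$coefficients$B - truth) / f$coefficients$std_error
  expect_true(all(dev < 3))
})

test_that("fit_mlr reports rank deficiency naming the collinear predictors", {
  set.seed(7)
  X <- data.frame(a = rnorm(30))
  X$b <- 2 * X$a
  expect_error(fit_mlr(X, rnorm(30)), "collinear.*b")
  expect_error(fit_mlr(data.frame(c = rep(1, 30)), rnorm(30)), "constant")
})

test_that("the fitted tables satisfy their own identities", {
  set.seed(12)
  X <- data.frame(p = rnorm(100), q = rnorm(100), s = rnorm(100))
  y <- 5 + X$p - 2 * X$q + rnorm(100)
  f <- fit_mlr(X, y)
  co <- f$coefficients
  expect_equal(co$t, co$B / co$std_error, tolerance = 1e-9)
  expect_equal(co$beta[-1],
               unname(co$B[-1] * vapply(X, sd, numeric(1)) / sd(y)),
               tolerance = 1e-9)
  expect_equal(f$summary$r, sqrt(f$summary$r_square), tolerance = 1e-12)
  expect_equal(co$vif[-1], 1 / co$tolerance[-1], tolerance = 1e-9)
  an <- f$anova
  expect_equal(an$ss_total, an$ss_regression + an$ss_residual,
               tolerance = 1e-6 * an$ss_total)
  expect_equal(an$df_total, an$df_regression + an$df_residual)
  # summary rebuilt from the fit's own sums of squares matches to 1e-9
  rebuilt <- anova_from_ss(an$ss_regression, an$df_regression,
                           an$ss_residual, an$df_residual)$summary
  for (nm in c("r", "r_square", "adj_r_square", "std_error_estimate", "p"))
    expect_equal(f$summary[[nm]], rebuilt[[nm]], tolerance = 1e-9)
})

test_that("fit_mlr diagnostics agree with independent implementations", {
  set.seed(21)
  X <- data.frame(a = rnorm(80), b = rnorm(80))
  X$c <- 0.7 * X$a + rnorm(80, sd = 0.5)
  y <- 1 + X$a + X$b + rnorm(80)
  f <- fit_mlr(X, y)
  lmf <- lm(y ~ a + b + c, data = cbind(X, y = y))
  expect_equal(unname(f$coefficients$vif[-1]), unname(car::vif(lmf)),
               tolerance = 1e-9)
  expect_equal(f$summary$durbin_watson,
               unname(lmtest::dwtest(lmf)$statistic), tolerance = 1e-9)
  ci <- confint(lmf)
  expect_equal(f$coefficients$ci_lower, unname(ci[, 1]), tolerance = 1e-9)
  expect_equal(f$coefficients$ci_upper, unname(ci[, 2]), tolerance = 1e-9)
})

test_that("ANOVA reconstruction from printed sums of squares is exact", {
  # image-biometry model: F(4, 379)
  a2 <- anova_from_ss(46427291.254, 4, 46138958.75, 379)
  expect_equal(round(a2$anova$F, 3), 95.342)
  expect_equal(round(a2$summary$r_square, 3), 0.502)
  expect_equal(round(a2$summary$r, 3), 0.708)
  expect_equal(round(a2$summary$adj_r_square, 3), 0.496)
  expect_equal(round(a2$summary$std_error_estimate, 3), 348.911)
  expect_lt(a2$anova$p, 0.001)
  # physician-biometry model: F(3, 380)
  a1 <- anova_from_ss(9943087.524, 3, 57246495.81, 380)
  expect_equal(round(a1$anova$F, 3), 22.001)
  expect_equal(round(a1$summary$r_square, 3), 0.148)
  expect_equal(round(a1$summary$std_error_estimate, 3), 388.135)
  # null model degenerates cleanly
  a0 <- anova_from_ss(0, 2, 100, 50)
  expect_equal(a0$anova$F, 0)
  expect_equal(a0$summary$r_square, 0)
  expect_equal(a0$anova$p, 1)
  expect_error(anova_from_ss(10, 0, 10, 5), "degrees")
})

test_that("collinearity diagnostics follow the closed forms", {
  set.seed(30)
  # orthogonal by construction
  X <- data.frame(a = rep(c(-1, 1), 20), b = rep(c(-1, -1, 1, 1), 10))
  cs <- collinearity_stats(X)
  expect_equal(cs$vif, c(1, 1), tolerance = 1e-9)
  dup <- data.frame(a = 1:10 + 0, b = 1:10 + 0)
  expect_true(all(is.infinite(collinearity_stats(dup)$vif)))
})

test_that("two predictors at correlation 0.9 give VIF 5.263", {
  # construct an exact r = 0.9 pair deterministically
  x1 <- c(scale(1:50))
  set.seed(1)
  e <- c(scale(resid(lm(rnorm(50) ~ x1))))
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * e
  expect_equal(cor(x1, x2), 0.9, tolerance = 1e-12)
  cs <- collinearity_stats(data.frame(x1 = x1, x2 = x2))
  expect_equal(cs$vif, c(1 / (1 - 0.81), 1 / (1 - 0.81)), tolerance = 1e-9)
  expect_equal(round(cs$vif[1], 3), 5.263)
})

test_that("Durbin-Watson matches hand arithmetic and the iid expectation", {
  expect_equal(durbin_watson(rep(5, 10)), 0)
  expect_equal(durbin_watson(rep(c(1, -1), 50)), 4 * 99 / 100)
  set.seed(8)
  expect_lt(abs(durbin_watson(rnorm(10000)) - 2), 0.1)
  expect_error(durbin_watson(rep(0, 5)), "zero")
  expect_error(durbin_watson(3), "two")
})

test_that("printed coefficient t-statistics are B over SE", {
  expect_equal(round(81.018 / 12.150, 3), 6.668)
  # and the package computes the same identity on its own fits
  set.seed(5)
  X <- data.frame(z = rnorm(40), w = rnorm(40))
  f <- fit_mlr(X, 2 + X$z + rnorm(40))
  expect_equal(f$coefficients$t, f$coefficients$B / f$coefficients$std_error)
})
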