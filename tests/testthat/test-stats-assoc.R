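test_that("group summaries use the n-1 SD and flag single values", {
  s <- group_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))
  s1 <- group_summary(5)
  expect_equal(s1$sem, 0)
  expect_false(s1$sem_defined)
  expect_equal(group_summary(c(4, 4, 4, 4))$sem, 0)
  expect_error(group_summary(numeric(0)), "No values")
})

test_that("pooled t-test matches the equal-variance reference and handles degeneracy", {
  tt <- ttest_pooled(c(1, 2, 3), c(4, 5, 6))
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(tt$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p.value, ref$p.value, tolerance = 1e-12)
  expect_equal(tt$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(tt$df, 4)

  withr::with_seed(2, { x <- rnorm(15); y <- rnorm(20, 0.4) })
  tt2 <- ttest_pooled(x, y)
  ref2 <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(tt2$p.value, ref2$p.value, tolerance = 1e-12)

  same <- c(2, 2, 2)
  expect_equal(ttest_pooled(same, same)$p.value, 1)
  deg <- ttest_pooled(c(1, 1, 1), c(2, 2, 2))
  expect_equal(deg$p.value, 0)
  expect_true(deg$degenerate)
  expect_error(ttest_pooled(1, c(1, 2)), "at least 2")
})

test_that("summary-statistic route reproduces printed worked examples", {
  # SHG collagen score: 62.52 +/- 2.74 (n=11) vs 51.77 +/- 3.49 (n=10)
  tt <- ttest_from_summary(62.52, 2.74, 11, 51.77, 3.49, 10)
  expect_equal(round(tt$p.value, 2), 0.02)
  expect_equal(tt$df, 19)
  # equal printed means give p = 1.00 exactly
  expect_equal(ttest_from_summary(1.000, 0.013, 22, 1.000, 0.017, 25)$p.value, 1)
  expect_error(ttest_from_summary(1, 0.1, 1, 2, 0.1, 5), "n >= 2")
  expect_error(ttest_from_summary(1, -0.1, 5, 2, 0.1, 5), "nonnegative")
})

test_that("summary route equals raw route on reduced datasets", {
  withr::with_seed(11, {
    for (k in 1:50) {
      x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
      y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
      raw <- ttest_pooled(x, y)
      sx <- group_summary(x); sy <- group_summary(y)
      red <- ttest_from_summary(sx$mean, sx$sem, sx$n, sy$mean, sy$sem, sy$n)
      expect_equal(red$statistic, raw$statistic, tolerance = 1e-12)
      expect_equal(red$p.value, raw$p.value, tolerance = 1e-12)
    }
  })
})

test_that("simple regression matches lm and handles degenerate input", {
  x <- 1:5; y <- 2 * x
  fit <- suppressWarnings(linreg(x, y))  # lm warns on a perfect fit
  expect_equal(fit$slope, 2)
  expect_equal(fit$slope_sem, 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1)

  withr::with_seed(4, { x <- rnorm(40); y <- 0.7 * x + rnorm(40) })
  fit2 <- linreg(x, y)
  ref <- summary(stats::lm(y ~ x))
  expect_equal(fit2$slope, unname(ref$coefficients["x", "Estimate"]))
  expect_equal(fit2$slope_sem, unname(ref$coefficients["x", "Std. Error"]))
  expect_equal(fit2$p, unname(ref$coefficients["x", "Pr(>|t|)"]))
  expect_equal(fit2$r2, ref$r.squared)

  expect_error(linreg(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(linreg(1:2, 1:2), "3 complete pairs")
  # listwise dropping of missing pairs
  expect_equal(linreg(c(x, NA), c(y, 1))$n, 40)
})

test_that("tidiers return broom-shaped tibbles", {
  tt <- ttest_pooled(c(1, 2, 3), c(4, 5, 6))
  td <- tidy(tt)
  expect_named(td, c("estimate", "estimate1", "estimate2", "statistic",
                     "df", "p.value", "method", "degenerate"))
  fit <- linreg(1:10, (1:10) * 0.5 + rnorm(10, sd = 1e-3))
  expect_equal(tidy(fit)$estimate, fit$slope)
  expect_equal(glance(fit)$r.squared, fit$r2)
})

test_that("association battery dispatches regressions and flag t-tests", {
  withr::with_seed(10, {
    rec <- tibble::tibble(
      metric = rnorm(60, 50, 8),
      age = rnorm(60, 70, 8),
      psa = rlnorm(60, log(4), 0.9),
      empty = NA_real_,
      flag = rep(c(TRUE, FALSE), 30)
    )
  })
  out <- run_association_battery(rec, "metric", c("age", "psa", "empty"),
                                 flags = "flag")
  expect_equal(nrow(out), 4)
  expect_equal(out$type, c("regression", "regression", "regression", "t-test"))
  expect_equal(out$note[out$covariate == "empty"], "insufficient data")
  age_row <- out[out$covariate == "age", ]
  ref <- linreg(rec$age, rec$metric)
  expect_equal(age_row$slope, ref$slope)
  expect_equal(age_row$p, ref$p)
  expect_equal(age_row$median, median(rec$age))
  flag_row <- out[out$covariate == "flag", ]
  ref_t <- ttest_pooled(rec$metric[rec$flag], rec$metric[!rec$flag])
  expect_equal(flag_row$p, ref_t$p.value)
  # optional BH adjustment adds a column, never reorders
  adj <- run_association_battery(rec, "metric", c("age", "psa"),
                                 flags = "flag", adjust = "BH")
  expect_true(all(adj$p_adj >= adj$p, na.rm = TRUE))
})
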