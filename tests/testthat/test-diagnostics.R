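test_that("paired t test matches hand computation and the closed form", {
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  res <- paired_t_test(c(1, 2, 3), c(1, 1, 1))
  expect_equal(res$t, sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$mean_diff, 1)

  flip <- paired_t_test(c(1, 1, 1), c(1, 2, 3))
  expect_equal(flip$t, -res$t)
  expect_equal(flip$p, res$p)

  # property: matches an independent one-liner on random pairs
  set.seed(24)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    obs <- stats::rnorm(n); pred <- stats::rnorm(n)
    r <- paired_t_test(obs, pred)
    d <- obs - pred
    t_ref <- mean(d) / (stats::sd(d) / sqrt(n))
    expect_equal(r$t, t_ref, tolerance = 1e-12)
    expect_equal(r$p, 2 * stats::pt(-abs(t_ref), n - 1), tolerance = 1e-12)
    expect_equal(r$df, n - 1)
    expect_equal(sign(r$t), sign(r$mean_diff))
  }

  zv <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_true(zv$zero_variance)
  expect_equal(zv$t, Inf)
  expect_error(paired_t_test(1, 2), "at least 2")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("Welch test reproduces the hand-computed statistic and df", {
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$t, 0)

  res <- welch_t_test(c(1, 2, 3), c(2, 4, 6))
  # var_a = 1, var_b = 4: t = -2 / sqrt(5/3), df = (5/3)^2 / ((1/9 + 16/9)/2)
  expect_equal(res$t, -2 / sqrt(5 / 3), tolerance = 1e-10)
  expect_equal(res$df, (5 / 3)^2 / ((1 / 3)^2 / 2 + (4 / 3)^2 / 2),
               tolerance = 1e-10)

  swap <- welch_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(swap$t, -res$t)
  expect_equal(swap$df, res$df)
  expect_equal(swap$p, res$p)
  expect_error(welch_t_test(1, c(2, 3)), "at least 2")
})

test_that("bias regression recovers intercept and slope against the normal equations", {
  perfect <- observed_vs_predicted_bias(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(perfect$intercept, 0, tolerance = 1e-12)
  expect_equal(perfect$slope, 1, tolerance = 1e-12)

  shift <- observed_vs_predicted_bias(c(6, 7, 8, 9), c(1, 2, 3, 4))
  expect_equal(shift$intercept, 5, tolerance = 1e-12)
  expect_equal(shift$slope, 1, tolerance = 1e-12)

  pred <- c(1, 3, 4, 7, 10)
  obs <- c(2.2, 3.1, 5.4, 7.9, 9.3)
  fit <- observed_vs_predicted_bias(obs, pred)
  # closed-form normal equations
  b <- sum((pred - mean(pred)) * (obs - mean(obs))) / sum((pred - mean(pred))^2)
  a <- mean(obs) - b * mean(pred)
  expect_equal(fit$slope, b, tolerance = 1e-12)
  expect_equal(fit$intercept, a, tolerance = 1e-12)

  expect_error(observed_vs_predicted_bias(1:5, rep(2, 5)), "constant")
  expect_error(observed_vs_predicted_bias(1:2, 1:2), "n >= 3")
})

test_that("chi-square(2) Q-Q pairs use the exponential-with-mean-2 quantiles", {
  q <- qq_chisq2(c(0.5, 1.2, 3.3, 7.1, 2.2))
  expect_equal(nrow(q), 5)
  expect_true(!is.unsorted(q$theoretical) && !is.unsorted(q$empirical))
  expect_equal(mean(q$empirical), 2)   # mean-matched by construction
  # theoretical quantiles are exactly -2 log(1 - p)
  p <- (seq_len(5) - 0.5) / 5
  expect_equal(q$theoretical, -2 * log(1 - p), tolerance = 1e-12)
  # the chi-square(2) median is 2 log 2
  q2 <- qq_chisq2(stats::rchisq(101, 2))
  expect_equal(q2$theoretical[51], 2 * log(2), tolerance = 1e-12)

  raw <- qq_chisq2(c(1, 2, 3), rescale = FALSE)
  expect_equal(raw$empirical, c(1, 2, 3))
  expect_error(qq_chisq2(c(-1, 2, 3)), "non-negative")
  expect_error(qq_chisq2(c(1, 2)), "n >= 3")
})

test_that("fit diagnostics bundle the bias line, Q-Q pairs and paired test", {
  crv <- gain_curve(50, 0.1)
  set.seed(25)
  T0 <- stats::runif(30, 2, 25)
  d <- tibble::tibble(patch_time_min = T0,
                      gain_euro = pmax(0.5, gain(crv, T0) + stats::rnorm(30, 2)))
  fit <- fit_gain_odr(d)
  dg <- diagnose_fit(fit)
  expect_s3_class(dg, "odr_diagnostics")
  expect_equal(nrow(dg$qq), 30)
  expect_equal(nrow(dg$residuals), 30)
  expect_true(is.finite(dg$bias$intercept) && is.finite(dg$bias$slope))
  expect_equal(dg$paired_t$test_kind, "paired")
  expect_s3_class(plot_qq(dg), "ggplot")
  expect_s3_class(plot_bias(dg), "ggplot")
})
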