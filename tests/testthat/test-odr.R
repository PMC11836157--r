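test_that("footpoints match a dense-sampling oracle and undercut vertical residuals", {
  crv <- gain_curve(50, 0.1)

  # point exactly on the curve
  on <- orthogonal_distance(crv, 10, gain(crv, 10))
  expect_equal(on$distance, 0, tolerance = 1e-9)
  expect_equal(on$footpoint, 10, tolerance = 1e-6)

  # reference point above the curve
  od <- orthogonal_distance(crv, 10, 40)
  vertical <- 40 - gain(crv, 10)
  T_grid <- seq(0, 40, by = 1e-4)
  oracle <- sqrt(min((T_grid - 10)^2 + (gain(crv, T_grid) - 40)^2))
  expect_equal(od$distance, oracle, tolerance = 1e-6)
  expect_lte(od$distance, vertical)
  expect_equal(od$signed_residual, od$distance)   # above the curve

  # small perturbations are bounded by the vertical offset
  eps <- 0.01
  near <- orthogonal_distance(crv, 15, gain(crv, 15) + eps)
  expect_lte(near$distance, eps)

  # batched points agree with the dense oracle too
  set.seed(20)
  T0 <- stats::runif(20, 0.5, 30)
  g0 <- gain(crv, T0) + stats::rnorm(20, sd = 6)
  batch <- orthogonal_distance(crv, T0, g0)
  for (i in 1:20) {
    o <- sqrt(oracle_min_dist2(50, 0.1, T0[i], g0[i], seq(0, 60, by = 5e-4)))
    expect_equal(batch$distance[i], o, tolerance = 1e-6)
  }
  expect_error(orthogonal_distance(crv, -1, 5), ">= 0")
})

test_that("residual statistics follow the df-corrected definition", {
  expect_equal(residual_stats(rep(0, 10)), list(s2 = 0, se = 0))
  rs <- residual_stats(c(3, 4), n_params = 0)
  expect_equal(rs$s2, 12.5)
  expect_equal(rs$se, sqrt(12.5))
  rs2 <- residual_stats(c(1, 2, 2, 3), n_params = 2)
  expect_equal(rs2$se^2, rs2$s2)
  expect_error(residual_stats(c(1, 2), n_params = 2), "more residuals")
})

test_that("noise-free data are fit exactly", {
  crv <- gain_curve(50, 0.1)
  d <- curve_points(crv, c(2, 5, 8, 12, 17, 25))
  fit <- fit_gain_odr(d)
  expect_equal(fit$A_hat, 50, tolerance = 1e-6)
  expect_equal(fit$k_hat, 0.1, tolerance = 1e-6)
  expect_lt(fit$objective, 1e-10)
  expect_true(fit$convergence$converged)
  td <- tidy(fit)
  expect_equal(td$estimate, c(fit$A_hat, fit$k_hat))
  expect_equal(glance(fit)$n, 6)
})

test_that("the fitted optimum matches an exhaustive grid search on small instances", {
  crv <- gain_curve(60, 0.12)
  T0 <- c(3, 6, 10, 15, 22)
  set.seed(21)
  d <- tibble::tibble(patch_time_min = T0,
                      gain_euro = gain(crv, T0) + c(1.5, -2, 0.8, -1.2, 2))
  fit <- fit_gain_odr(d)
  oracle <- oracle_grid_fit(d$patch_time_min, d$gain_euro)
  expect_equal(fit$objective, oracle$objective,
               tolerance = 0.02 * oracle$objective)
  expect_equal(fit$A_hat, oracle$A, tolerance = 0.05 * oracle$A)
  expect_equal(fit$k_hat, oracle$k, tolerance = 0.05 * oracle$k)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_gain_odr(tibble::tibble(patch_time_min = c(1, 2),
                                           gain_euro = c(1, 2))),
               "at least 3")
  expect_error(fit_gain_odr(tibble::tibble(patch_time_min = c(5, 5, 5),
                                           gain_euro = c(1, 2, 3))),
               "degenerate")
})

test_that("the ODR objective undercuts the vertical least-squares estimates", {
  crv <- gain_curve(45, 0.09)
  set.seed(22)
  T0 <- stats::runif(25, 2, 28)
  d <- tibble::tibble(patch_time_min = T0,
                      gain_euro = pmax(0.5, gain(crv, T0) + stats::rnorm(25, sd = 3)))
  fit <- fit_gain_odr(d)
  ols <- minpack.lm::nlsLM(gain_euro ~ A * (1 - exp(-k * patch_time_min)),
                           data = d, start = list(A = 50, k = 0.1))
  co <- stats::coef(ols)
  ols_obj <- sum(orthogonal_distance(gain_curve(co[["A"]], co[["k"]]),
                                     d$patch_time_min, d$gain_euro)$distance^2)
  expect_lte(fit$objective, ols_obj + 1e-8)
})

test_that("the fit depends on the gain-axis scale (orthogonal distance mixes units)", {
  crv <- gain_curve(45, 0.09)
  set.seed(23)
  T0 <- stats::runif(20, 2, 28)
  d <- tibble::tibble(patch_time_min = T0,
                      gain_euro = pmax(0.5, gain(crv, T0) + stats::rnorm(20, sd = 3)))
  f1 <- fit_gain_odr(d)
  d2 <- dplyr::mutate(d, gain_euro = gain_euro * 3)
  f2 <- fit_gain_odr(d2)
  # a scale-equivariant fit would give exactly A_hat * 3 and the same k_hat;
  # orthogonal distance is not equivariant, so the rescaled fit must differ
  expect_gt(abs(f2$A_hat - 3 * f1$A_hat) / (3 * f1$A_hat) +
              abs(f2$k_hat - f1$k_hat) / f1$k_hat, 1e-4)
  # standardized fitting is insensitive to the same rescaling
  s1 <- fit_gain_odr(d, standardize = TRUE)
  s2 <- fit_gain_odr(d2, standardize = TRUE)
  expect_equal(s2$A_hat, 3 * s1$A_hat, tolerance = 1e-4)
  expect_equal(s2$k_hat, s1$k_hat, tolerance = 1e-4)
})

test_that("augment returns footpoints consistent with the fitted curve", {
  crv <- gain_curve(50, 0.1)
  d <- curve_points(crv, c(2, 6, 11, 18))
  fit <- fit_gain_odr(d)
  aug <- augment(fit)
  expect_equal(aug$fitted_gain, gain(fit$curve, aug$footpoint))
  expect_equal(nrow(aug), 4)
})
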