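ttest_tibble <- function(t, df, p, mean_diff, kind, zero_variance = FALSE) {
  tibble::tibble(t = t, df = df, p = p, mean_diff = mean_diff,
                 test_kind = kind, zero_variance = zero_variance)
}

#' Paired two-tailed t test
#'
#' Compares observed and model-predicted values record by record: a standard
#' paired t test on the differences with `df = n - 1`. A non-significant
#' result is the model-consistent outcome — predictions and reports agree up
#' to symmetric noise.
#'
#' @param observed,predicted Numeric vectors of equal length (paired by
#'   record), `n >= 2`.
#' @return A one-row tibble: `t`, `df`, `p` (two-tailed), `mean_diff`
#'   (mean of observed - predicted), `test_kind = "paired"`, and a
#'   `zero_variance` flag (when all differences are identical the statistic
#'   is `0` for a zero mean and signed `Inf` otherwise).
#' @export
paired_t_test <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  ok <- !is.na(observed) & !is.na(predicted)
  d <- observed[ok] - predicted[ok]
  n <- length(d)
  if (n < 2) stop("paired t test needs at least 2 complete pairs", call. = FALSE)
  m <- mean(d)
  if (stats::sd(d) == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    return(ttest_tibble(t, n - 1, if (m == 0) 1 else 0, m, "paired",
                        zero_variance = TRUE))
  }
  ht <- stats::t.test(d, mu = 0, alternative = "two.sided")
  ttest_tibble(unname(ht$statistic), unname(ht$parameter), ht$p.value, m, "paired")
}

#' Welch two-sample t test
#'
#' Group comparison without assuming equal variances: Welch statistic with
#' Satterthwaite (fractional) degrees of freedom, two-tailed.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 non-missing
#'   values.
#' @return A one-row tibble as in [paired_t_test()] with
#'   `test_kind = "welch"`; `mean_diff` is `mean(a) - mean(b)`.
#' @export
welch_t_test <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    m <- mean(a) - mean(b)
    t <- if (m == 0) 0 else sign(m) * Inf
    return(ttest_tibble(t, length(a) + length(b) - 2, if (m == 0) 1 else 0,
                        m, "welch", zero_variance = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  ttest_tibble(unname(ht$statistic), unname(ht$parameter), ht$p.value,
               mean(a) - mean(b), "welch",
               zero_variance = stats::sd(a) == 0 || stats::sd(b) == 0)
}

#' Observed-versus-predicted bias regression
#'
#' Ordinary least squares of the observed values (y) on the predicted values
#' (x). Under an unbiased model the intercept is 0 and the slope 1; a
#' non-zero intercept indicates systematic bias, a slope away from 1
#' proportional over- or under-prediction.
#'
#' @param observed,predicted Numeric vectors of equal length, `n >= 3`;
#'   predictions must not be constant.
#' @return A list with `intercept`, `slope`, the `lm` object (`model`), and
#'   `line_data`, a two-column tibble tracing the identity line over the
#'   prediction range for plotting.
#' @export
observed_vs_predicted_bias <- function(observed, predicted) {
  ok <- !is.na(observed) & !is.na(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  if (length(observed) < 3) stop("bias regression needs n >= 3", call. = FALSE)
  if (stats::sd(predicted) == 0) {
    stop("predictions are constant; bias regression undefined", call. = FALSE)
  }
  fit <- stats::lm(observed ~ predicted)
  co <- unname(stats::coef(fit))
  rng <- range(predicted)
  list(intercept = co[1], slope = co[2], model = fit,
       line_data = tibble::tibble(predicted = rng, observed = rng))
}

#' Chi-square(2) Q-Q pairs for squared orthogonal residuals
#'
#' Compares the distribution of squared residual lengths to a chi-square
#' distribution with two degrees of freedom (equivalently, exponential with
#' mean 2: quantile function `-2 log(1 - p)`). Because the residuals carry an
#' arbitrary scale, the empirical values are by default rescaled by
#' `mean / 2` so their mean matches the chi-square(2) mean of 2; set
#' `rescale = FALSE` for the raw comparison.
#'
#' @param squared_residuals Non-negative numeric vector, `n >= 3`.
#' @param rescale Mean-match the empirical values to the reference mean of 2?
#' @param positions Plotting positions: `"midpoint"` for `(i - 0.5)/n`
#'   (default) or `"blom"` for `(i - 3/8)/(n + 1/4)`.
#' @return A tibble of sorted pairs: `theoretical` (chi-square(2) quantiles)
#'   and `empirical`.
#' @export
qq_chisq2 <- function(squared_residuals,
                      rescale = TRUE,
                      positions = c("midpoint", "blom")) {
  positions <- match.arg(positions)
  x <- squared_residuals[!is.na(squared_residuals)]
  if (any(x < 0)) stop("squared residuals must be non-negative", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("Q-Q comparison needs n >= 3", call. = FALSE)
  if (rescale) x <- x / (mean(x) / 2)
  p <- if (positions == "midpoint") (seq_len(n) - 0.5) / n
       else (seq_len(n) - 3 / 8) / (n + 1 / 4)
  tibble::tibble(theoretical = stats::qchisq(p, df = 2),
                 empirical = sort(x))
}

#' Residual diagnostics for a fitted gain curve
#'
#' Bundles the residual checks applied to an [fit_gain_odr()] result: the
#' observed-versus-predicted bias regression, the chi-square(2) Q-Q pairs of
#' the squared orthogonal residuals, Freedman-Diaconis histogram bin edges,
#' and the paired t test of observed against predicted gains.
#'
#' @param fit An `odr_fit`.
#' @return A list of class `odr_diagnostics`: `bias` (intercept/slope),
#'   `qq` (pair tibble), `hist_breaks`, `paired_t` (one-row tibble), and the
#'   augmented residual table `residuals`.
#' @export
diagnose_fit <- function(fit) {
  if (!inherits(fit, "odr_fit")) stop("`fit` must be an odr_fit", call. = FALSE)
  aug <- augment(fit)
  predicted <- gain(fit$curve, aug$T_obs)
  bias <- observed_vs_predicted_bias(aug$g_obs, predicted)
  sq <- aug$distance^2
  qq <- qq_chisq2(sq)
  breaks <- grDevices::nclass.FD(sq)
  structure(list(
    bias = bias[c("intercept", "slope")],
    bias_model = bias$model,
    qq = qq,
    hist_breaks = breaks,
    paired_t = paired_t_test(aug$g_obs, predicted),
    residuals = dplyr::mutate(aug, predicted_gain = predicted)
  ), class = "odr_diagnostics")
}

#' @export
print.odr_diagnostics <- function(x, ...) {
  cat("Residual diagnostics for the gain-curve ODR fit\n")
  cat(sprintf("  bias regression: intercept = %.3f, slope = %.3f\n",
              x$bias$intercept, x$bias$slope))
  pt <- x$paired_t
  cat(sprintf("  paired t (observed vs predicted gain): t = %.3f, df = %g, p = %.3f\n",
              pt$t, pt$df, pt$p))
  invisible(x)
}

#' Q-Q panel of squared orthogonal residuals
#'
#' @param diag An `odr_diagnostics` (or any object with a `$qq` pair tibble).
#' @return A ggplot object with the identity reference line.
#' @export
plot_qq <- function(diag) {
  qq <- if (is.data.frame(diag)) diag else diag$qq
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$theoretical, y = .data$empirical)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Chi-square(2) quantiles", y = "Squared residuals (rescaled)",
                  title = "Q-Q plot of squared orthogonal residuals") +
    ggplot2::theme_minimal()
}

#' Observed-versus-predicted panel
#'
#' @param diag An `odr_diagnostics`.
#' @return A ggplot object: observed against predicted values with the
#'   identity line (grey) and the bias regression line (blue).
#' @export
plot_bias <- function(diag) {
  d <- diag$residuals
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted_gain, y = .data$g_obs)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = diag$bias$slope, intercept = diag$bias$intercept,
                         colour = "#2166ac") +
    ggplot2::labs(x = "Predicted gain (Euro)", y = "Observed gain (Euro)",
                  title = "Observed versus predicted gain") +
    ggplot2::theme_minimal()
}
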