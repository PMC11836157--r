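#' Evaluate travel-time predictions from a fitted gain curve
#'
#' The second model prediction: with `(A_hat, k_hat)` estimated from the
#' gain data, each record's residence time implies an MVT-optimal signed
#' travel time `t_pred = T - g(T)/g'(T)` (see [predict_travel_time()]; the
#' result depends only on `k_hat`). Reported round-trip travel times are
#' negated onto the model's signed convention and compared with the
#' predictions: vertical residuals `t_obs - t_pred`, their variance
#' statistics with `n - 2` degrees of freedom (two fitted parameters), and a
#' paired t test of observed against predicted times.
#'
#' @param fit An [fit_gain_odr()] result.
#' @param records A data frame with positive reported travel and residence
#'   times.
#' @param travel,time Column names of the reported round-trip travel time
#'   and residence time (both positive minutes).
#' @param absolute Compare absolute instead of signed travel times in the
#'   residuals and t test? Default `FALSE` (signed, matching the negative-
#'   axis plotting convention).
#' @return An object of class `travel_eval`: a list with `residual_table`
#'   (per-record `T`, `t_obs`, `t_pred`, `residual`), `s2`, `se`,
#'   `paired_t` (one-row tibble), and `n`.
#' @export
evaluate_travel_predictions <- function(fit, records,
                                        travel = "travel_time_min",
                                        time = "patch_time_min",
                                        absolute = FALSE) {
  if (!inherits(fit, "odr_fit")) stop("`fit` must be an odr_fit", call. = FALSE)
  if (!all(c(travel, time) %in% names(records))) {
    stop("`records` must contain columns `", travel, "` and `", time, "`",
         call. = FALSE)
  }
  T_obs <- as.numeric(records[[time]])
  rep_travel <- as.numeric(records[[travel]])
  ok <- !is.na(T_obs) & !is.na(rep_travel)
  T_obs <- T_obs[ok]; rep_travel <- rep_travel[ok]
  if (any(T_obs <= 0)) {
    stop("non-positive residence times present; run exclusion/filters first",
         call. = FALSE)
  }
  if (any(rep_travel <= 0)) {
    stop("reported travel times must be positive minutes", call. = FALSE)
  }
  t_pred <- predict_travel_time(fit$curve, T_obs)
  t_obs <- -rep_travel
  if (absolute) {
    t_pred <- abs(t_pred)
    t_obs <- abs(t_obs)
  }
  resid <- t_obs - t_pred
  rs <- residual_stats(resid, n_params = 2)
  structure(list(
    residual_table = tibble::tibble(T = T_obs, t_obs = t_obs,
                                    t_pred = t_pred, residual = resid),
    s2 = rs$s2, se = rs$se, n = length(resid),
    absolute = absolute,
    paired_t = paired_t_test(t_obs, t_pred)
  ), class = "travel_eval")
}

#' @export
print.travel_eval <- function(x, ...) {
  cat("Travel-time predictions from the fitted gain curve\n")
  cat(sprintf("  n = %d   s2 = %.4f   se = %.4f\n", x$n, x$s2, x$se))
  pt <- x$paired_t
  cat(sprintf("  paired t (observed vs predicted): t = %.3f, df = %g, p = %.3f\n",
              pt$t, pt$df, pt$p))
  invisible(x)
}

#' One-row summary of a travel-time evaluation
#'
#' @param x A `travel_eval`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `s2`, `se`, `t`, `df`, `p`, `mean_resid`.
#' @export
glance.travel_eval <- function(x, ...) {
  tibble::tibble(n = x$n, s2 = x$s2, se = x$se,
                 t = x$paired_t$t, df = x$paired_t$df, p = x$paired_t$p,
                 mean_resid = mean(x$residual_table$residual))
}

#' Per-record travel residuals
#'
#' @param x A `travel_eval`.
#' @param ... Unused.
#' @return The residual tibble: `T`, `t_obs`, `t_pred`, `residual`.
#' @export
augment.travel_eval <- function(x, ...) x$residual_table

#' Plot observed and predicted travel times against residence time
#'
#' @param object A `travel_eval`.
#' @param ... Unused.
#' @return A ggplot object: observed signed travel times (points) and the
#'   tangent-construction prediction curve.
#' @export
autoplot.travel_eval <- function(object, ...) {
  d <- object$residual_table
  ord <- order(d$T)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$T, y = .data$t_obs)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = d[ord, ],
                       ggplot2::aes(x = .data$T, y = .data$t_pred),
                       colour = "#2166ac", linewidth = 1) +
    ggplot2::labs(x = "Patch residence time (min)",
                  y = "Signed travel time (min)",
                  title = "Observed and predicted travel times") +
    ggplot2::theme_minimal()
}
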