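# Footpoint machinery for orthogonal-distance regression.
#
# For a point (T0, g0) and curve g(T) = A(1 - exp(-kT)), the footpoint T*
# minimises psi(T) = (T - T0)^2 + (g(T) - g0)^2 over T >= 0. Since the
# minimal distance cannot exceed the vertical residual, T* always lies in
# [max(0, T0 - v), T0 + v] with v = |g(T0) - g0|. Inside that bracket we
# locate the minimum by a coarse grid scan (guards against multiple local
# minima on strongly curved instances), shrink with golden-section steps,
# and polish with safeguarded Newton on the stationarity condition
# phi(T) = (T - T0) + g'(T) (g(T) - g0) = 0.
odr_footpoints <- function(A, k, T0, g0, n_grid = 33L, n_golden = 45L,
                           n_newton = 3L) {
  gfun <- function(T) A * (1 - exp(-k * T))
  gp <- function(T) A * k * exp(-k * T)
  gpp <- function(T) -A * k * k * exp(-k * T)
  psi <- function(T) (T - T0)^2 + (gfun(T) - g0)^2
  vert <- abs(gfun(T0) - g0)
  lo <- pmax(0, T0 - vert)
  hi <- T0 + vert
  width <- hi - lo

  # coarse scan
  s <- seq(0, 1, length.out = n_grid)
  Tg <- outer(s, width) + rep(lo, each = n_grid)       # n_grid x n
  psig <- (Tg - rep(T0, each = n_grid))^2 +
    (A * (1 - exp(-k * Tg)) - rep(g0, each = n_grid))^2
  jmin <- max.col(-t(psig), ties.method = "first")
  a <- Tg[cbind(pmax(jmin - 1L, 1L), seq_along(T0))]
  b <- Tg[cbind(pmin(jmin + 1L, n_grid), seq_along(T0))]

  # golden-section shrink
  gs <- (sqrt(5) - 1) / 2
  x1 <- b - gs * (b - a); x2 <- a + gs * (b - a)
  f1 <- psi(x1); f2 <- psi(x2)
  for (i in seq_len(n_golden)) {
    m1 <- f1 < f2
    b <- ifelse(m1, x2, b)
    a <- ifelse(m1, a, x1)
    nx1 <- b - gs * (b - a)
    nx2 <- a + gs * (b - a)
    fe <- psi(ifelse(m1, nx1, nx2))
    f1n <- ifelse(m1, fe, f2)
    f2n <- ifelse(m1, f1, fe)
    x1 <- nx1; x2 <- nx2; f1 <- f1n; f2 <- f2n
  }
  Tstar <- (a + b) / 2

  # Newton polish on phi
  for (i in seq_len(n_newton)) {
    gT <- gfun(Tstar)
    phi <- (Tstar - T0) + gp(Tstar) * (gT - g0)
    dphi <- 1 + gp(Tstar)^2 + gpp(Tstar) * (gT - g0)
    step <- ifelse(is.finite(dphi) & dphi > 0, phi / dphi, 0)
    Tstar <- pmax(0, Tstar - step)
  }
  Tstar <- pmax(0, pmin(Tstar, hi))
  gT <- gfun(Tstar)
  dist <- sqrt((Tstar - T0)^2 + (gT - g0)^2)
  list(footpoint = Tstar, distance = dist,
       signed = sign(g0 - gT) * dist, vertical = vert)
}

#' Orthogonal distance from data points to the gain curve
#'
#' For each observed pair (residence time, gain), finds the footpoint — the
#' nearest point on the curve — and the Euclidean length `||D||` of the
#' orthogonal distance vector. This mixes axis units (minutes and Euro), the
#' natural choice when both coordinates carry comparable reporting error; the
#' orthogonal distance never exceeds the vertical residual.
#'
#' @param curve A [gain_curve()].
#' @param T_obs Observed residence times (minutes, >= 0), vectorised.
#' @param g_obs Observed gains (Euro), vectorised.
#' @return A tibble with columns `T_obs`, `g_obs`, `footpoint` (abscissa of
#'   the nearest curve point), `distance` (`||D||`), and `signed_residual`
#'   (`||D||` signed by whether the point lies above or below the curve).
#' @export
orthogonal_distance <- function(curve, T_obs, g_obs) {
  check_curve(curve)
  if (any(T_obs < 0, na.rm = TRUE)) stop("`T_obs` must be >= 0", call. = FALSE)
  if (anyNA(T_obs) || anyNA(g_obs)) stop("missing values in input points", call. = FALSE)
  fp <- odr_footpoints(curve$A, curve$k, T_obs, g_obs)
  tibble::tibble(T_obs = T_obs, g_obs = g_obs,
                 footpoint = fp$footpoint, distance = fp$distance,
                 signed_residual = fp$signed)
}

#' Residual variance and standard error from orthogonal residual lengths
#'
#' `s2 = sum(||D||^2) / (n - n_params)` and `se = sqrt(s2)`, the two summary
#' statistics reported for each fitted model.
#'
#' @param residual_lengths Numeric vector of residual lengths `||D||`.
#' @param n_params Number of fitted parameters consumed as degrees of
#'   freedom (2 for the gain curve).
#' @return A list with elements `s2` and `se`.
#' @export
residual_stats <- function(residual_lengths, n_params = 2) {
  n <- length(residual_lengths)
  if (n <= n_params) {
    stop("need more residuals (", n, ") than parameters (", n_params, ")",
         call. = FALSE)
  }
  s2 <- sum(residual_lengths^2) / (n - n_params)
  list(s2 = s2, se = sqrt(s2))
}

#' Fit the gain curve by nonlinear orthogonal-distance regression
#'
#' Estimates `(A, k)` of `g(T) = A (1 - exp(-kT))` by minimising the sum of
#' squared orthogonal distances from the observed (residence time, gain)
#' pairs to the curve — the errors-in-variables analogue of least squares,
#' appropriate because both coordinates are self-reported estimates. The
#' optimisation is nested: an outer Nelder-Mead search over `(log A, log k)`
#' (which keeps both parameters positive) around an inner exact footpoint
#' solve for every point; footpoints are recomputed at the optimum.
#'
#' Orthogonal distance mixes the axis units, so the fit is scale-dependent:
#' rescaling the gain axis changes footpoints and estimates. By default the
#' raw minutes/Euro units are used; `standardize = TRUE` scales both axes to
#' unit variance before fitting (sensitivity analysis) and maps the
#' estimates back.
#'
#' @param data A data frame of observations.
#' @param time,gain Column names (strings) holding residence time (minutes)
#'   and gain; defaults `"patch_time_min"`, `"gain_euro"`.
#' @param init Optional numeric `c(A0, k0)` starting values. Default:
#'   `A0 = 1.1 * max(gain)`, `k0 = mean(gain) / (A0 * mean(time))` clipped
#'   to `[1e-4, 10]`.
#' @param standardize Fit on unit-variance axes? Default `FALSE`.
#' @param reltol Relative objective-change convergence tolerance of the
#'   outer search.
#' @param max_iter Outer iteration budget.
#' @return An object of class `odr_fit`: a list with `A_hat`, `k_hat`,
#'   `footpoints` (the [orthogonal_distance()] tibble at the optimum),
#'   `objective` (sum of squared `||D||`), `s2`, `se`, `n`, `data`, and
#'   `convergence` (outer iteration count and convergence flag).
#' @examples
#' crv <- gain_curve(50, 0.1)
#' d <- tibble::tibble(patch_time_min = c(2, 5, 9, 14, 20),
#'                     gain_euro = gain(crv, c(2, 5, 9, 14, 20)))
#' fit <- fit_gain_odr(d)
#' glance(fit)
#' @export
fit_gain_odr <- function(data, time = "patch_time_min", gain = "gain_euro",
                         init = NULL, standardize = FALSE,
                         reltol = 1e-10, max_iter = 500L) {
  if (!all(c(time, gain) %in% names(data))) {
    stop("`data` must contain columns `", time, "` and `", gain, "`",
         call. = FALSE)
  }
  T_obs <- as.numeric(data[[time]])
  g_obs <- as.numeric(data[[gain]])
  keep <- !is.na(T_obs) & !is.na(g_obs)
  T_obs <- T_obs[keep]; g_obs <- g_obs[keep]
  n <- length(T_obs)
  if (n < 3) stop("ODR fit needs at least 3 observations, got ", n, call. = FALSE)
  if (length(unique(T_obs)) < 2) {
    stop("degenerate design: all residence times identical", call. = FALSE)
  }
  sT <- if (standardize) stats::sd(T_obs) else 1
  sG <- if (standardize) stats::sd(g_obs) else 1
  Tw <- T_obs / sT; gw <- g_obs / sG

  if (is.null(init)) {
    A0 <- 1.1 * max(gw)
    k0 <- min(10, max(1e-4, mean(gw) / (A0 * mean(Tw))))
  } else {
    A0 <- init[1] / sG
    k0 <- init[2] * sT
    if (A0 <= 0 || k0 <= 0) stop("`init` values must be positive", call. = FALSE)
  }

  objective <- function(theta, fast = TRUE) {
    A <- exp(theta[1]); k <- exp(theta[2])
    fp <- if (fast) {
      odr_footpoints(A, k, Tw, gw, n_grid = 21L, n_golden = 30L, n_newton = 2L)
    } else {
      odr_footpoints(A, k, Tw, gw)
    }
    sum(fp$distance^2)
  }
  opt <- stats::optim(c(log(A0), log(k0)), objective,
                      method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = reltol))
  # polish with full-precision footpoints from the converged point
  opt2 <- stats::optim(opt$par, objective, fast = FALSE,
                       method = "Nelder-Mead",
                       control = list(maxit = 200L, reltol = reltol))
  if (opt2$value <= opt$value) {
    opt2$counts <- opt$counts + opt2$counts
    opt2$convergence <- min(opt$convergence, opt2$convergence)
    opt <- opt2
  }
  A_hat <- exp(opt$par[1]) * sG
  k_hat <- exp(opt$par[2]) / sT

  curve <- gain_curve(A_hat, k_hat)
  fp <- orthogonal_distance(curve, T_obs, g_obs)
  objective_val <- sum(fp$distance^2)
  rs <- residual_stats(fp$distance, n_params = 2)

  structure(list(
    A_hat = A_hat, k_hat = k_hat, curve = curve,
    footpoints = fp, objective = objective_val,
    s2 = rs$s2, se = rs$se, n = n,
    standardize = standardize,
    data = tibble::tibble(!!time := T_obs, !!gain := g_obs),
    time_col = time, gain_col = gain,
    convergence = list(iterations = opt$counts[["function"]],
                       converged = opt$convergence == 0,
                       message = opt$message %||% "")
  ), class = "odr_fit")
}

#' @export
print.odr_fit <- function(x, ...) {
  cat("Nonlinear orthogonal-distance regression: g(T) = A (1 - exp(-k T))\n")
  cat(sprintf("  n = %d   A_hat = %.4f   k_hat = %.5f\n", x$n, x$A_hat, x$k_hat))
  cat(sprintf("  sum ||D||^2 = %.4f   s2 = %.4f   se = %.4f\n",
              x$objective, x$s2, x$se))
  if (!x$convergence$converged) cat("  WARNING: outer search did not converge\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy the parameter estimates of an ODR fit
#'
#' @param x An `odr_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.odr_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "k"), estimate = c(x$A_hat, x$k_hat))
}

#' One-row summary of an ODR fit
#'
#' @param x An `odr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `A_hat`, `k_hat`, `objective`, `s2`, `se`,
#'   `n`, `converged`.
#' @export
glance.odr_fit <- function(x, ...) {
  tibble::tibble(A_hat = x$A_hat, k_hat = x$k_hat, objective = x$objective,
                 s2 = x$s2, se = x$se, n = x$n,
                 converged = x$convergence$converged)
}

#' Per-observation footpoints and residuals of an ODR fit
#'
#' @param x An `odr_fit`.
#' @param ... Unused.
#' @return The footpoint tibble: observed pair, footpoint abscissa,
#'   `distance` (`||D||`), `signed_residual`, and `fitted_gain` (curve value
#'   at the footpoint).
#' @export
augment.odr_fit <- function(x, ...) {
  dplyr::mutate(x$footpoints, fitted_gain = gain(x$curve, .data$footpoint))
}

#' Plot an ODR fit: data, fitted curve and a linear comparison
#'
#' Scatter of the observed pairs with the fitted asymptotic gain curve and,
#' for visual comparison, an ordinary linear regression line.
#'
#' @param object An `odr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.odr_fit <- function(object, ...) {
  d <- object$data
  names(d) <- c("T_obs", "g_obs")
  grid <- tibble::tibble(T_obs = seq(0, max(d$T_obs) * 1.05, length.out = 200))
  grid$g_fit <- gain(object$curve, grid$T_obs)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$T_obs, y = .data$g_obs)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$T_obs, y = .data$g_fit),
                       colour = "#2166ac", linewidth = 1) +
    ggplot2::labs(x = "Patch residence time (min)", y = "Gain (Euro)",
                  title = "Orthogonal-distance fit of the gain curve",
                  subtitle = "dashed grey: ordinary linear regression") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
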