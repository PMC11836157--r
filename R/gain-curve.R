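#' Asymptotic gain curve for a resource patch
#'
#' Constructs the two-parameter gain curve \eqn{g(T) = A (1 - e^{-kT})} used
#' throughout the package: cumulative gain rises from zero with initial rate
#' \eqn{A k} and saturates at the asymptote \eqn{A} as patch residence time
#' \eqn{T} grows. The curve is strictly increasing and strictly concave, the
#' "diminishing returns" shape the marginal value theorem assumes.
#'
#' @param A Maximum attainable gain in the patch (Euro, or a product count
#'   when gain is operationalised as number of products). Must be positive.
#' @param k Initial gain-rate parameter (1/minute). Must be positive.
#'
#' @return An object of class `gain_curve`: a list with elements `A` and `k`.
#' @examples
#' crv <- gain_curve(A = 50, k = 0.1)
#' gain(crv, T = 10)
#' @export
gain_curve <- function(A, k) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(k), length(k) == 1L, is.finite(k))
  if (A <= 0) stop("`A` must be positive, got ", A, call. = FALSE)
  if (k <= 0) stop("`k` must be positive, got ", k, call. = FALSE)
  structure(list(A = as.numeric(A), k = as.numeric(k)), class = "gain_curve")
}

#' @export
print.gain_curve <- function(x, ...) {
  cat(sprintf("<gain_curve> g(T) = %.4g * (1 - exp(-%.4g * T))\n", x$A, x$k))
  invisible(x)
}

check_curve <- function(curve) {
  if (!inherits(curve, "gain_curve")) {
    stop("expected a `gain_curve` object; see gain_curve()", call. = FALSE)
  }
  curve
}

#' Cumulative gain after a given residence time
#'
#' Evaluates \eqn{g(T) = A (1 - e^{-kT})}, the cumulative gain a forager has
#' obtained after spending `T` minutes in the patch.
#'
#' @param curve A [gain_curve()].
#' @param T Patch residence time in minutes; vectorised, all values >= 0.
#' @return Numeric vector of gains in the curve's gain unit; in `[0, A)`.
#' @export
gain <- function(curve, T) {
  check_curve(curve)
  if (any(T < 0, na.rm = TRUE)) stop("residence time `T` must be >= 0", call. = FALSE)
  curve$A * (1 - exp(-curve$k * T))
}

#' Marginal gain rate at a given residence time
#'
#' The instantaneous gain rate \eqn{g'(T) = A k e^{-kT}}, strictly decreasing
#' in `T`. Under the MVT the forager should leave the patch when this marginal
#' rate drops to the long-run average rate.
#'
#' @inheritParams gain
#' @return Numeric vector of gain rates (gain unit per minute).
#' @export
gain_rate <- function(curve, T) {
  check_curve(curve)
  if (any(T < 0, na.rm = TRUE)) stop("residence time `T` must be >= 0", call. = FALSE)
  curve$A * curve$k * exp(-curve$k * T)
}

#' Travel time implied by an optimal residence time
#'
#' Under the tangent construction of the marginal value theorem, a residence
#' time `T` is optimal exactly when the tangent to the gain curve at
#' \eqn{(T, g(T))} passes through \eqn{(t, 0)}, where `t` is the (signed)
#' round-trip travel time. Solving \eqn{t = T - g(T)/g'(T)} for the
#' exponential curve gives \eqn{t = T - (e^{kT} - 1)/k}, which is negative for
#' every `T > 0`: travel time is plotted on the negative time axis in this
#' analysis's convention. The result does not depend on the asymptote `A`
#' (it cancels in \eqn{g/g'}).
#'
#' @inheritParams gain
#' @param T Residence time in minutes; vectorised, all values > 0.
#' @return Signed travel time in minutes (negative).
#' @seealso [solve_residence_time()] for the inverse direction.
#' @export
predict_travel_time <- function(curve, T) {
  check_curve(curve)
  if (any(T <= 0, na.rm = TRUE)) stop("residence time `T` must be > 0", call. = FALSE)
  T - expm1(curve$k * T) / curve$k
}

#' Optimal residence time implied by a travel time
#'
#' Inverts the tangent condition: given a signed travel time `t <= 0`, finds
#' the unique residence time `T >= 0` with \eqn{e^{kT} = k (T - t) + 1}. The
#' root is unique because \eqn{f(T) = e^{kT} - kT + kt - 1} has
#' \eqn{f(0) = kt \le 0} and is strictly increasing past the origin. Solved
#' by a bracketed Newton iteration (bisection fallback), with the bracket
#' expanded geometrically until a sign change is found.
#'
#' @inheritParams gain
#' @param t Signed round-trip travel time in minutes; vectorised, all
#'   values <= 0 (this package's convention puts travel on the negative axis).
#' @param tol Convergence tolerance on the implicit-equation residual,
#'   relative to `1 + T` (the residual is expressed in minutes via the log
#'   form of the equation).
#' @param max_iter Iteration budget for the root finder.
#' @return Residence times in minutes (>= 0), same length as `t`.
#' @export
solve_residence_time <- function(curve, t, tol = 1e-10, max_iter = 200L) {
  check_curve(curve)
  if (any(!is.finite(t))) stop("travel time `t` must be finite", call. = FALSE)
  if (any(t > 0)) stop("travel time `t` must be <= 0 (signed convention)", call. = FALSE)
  k <- curve$k
  # solve the log form T = log1p(k (T - t)) / k: its residual
  # h(T) = T - log1p(k (T - t)) / k is scaled in minutes, increasing, with
  # h(0) <= 0, so Newton with a bracketed bisection fallback is safe
  h <- function(T) T - log1p(k * (T - t)) / k
  hp <- function(T) 1 - 1 / (1 + k * (T - t))
  lo <- rep(0, length(t))
  hi <- log1p(k * (1 - t)) / k + 10 / k
  for (i in 1:60) {
    bad <- h(hi) < 0
    if (!any(bad)) break
    hi[bad] <- hi[bad] * 2
  }
  x <- pmin(hi, pmax(lo, log1p(-k * t) / k))  # fixed-point seed
  step <- rep(Inf, length(t))
  for (iter in seq_len(max_iter)) {
    hx <- h(x)
    done <- abs(step) < 1e-12 * (1 + abs(x)) | abs(hx) < .Machine$double.eps * (1 + abs(x))
    if (all(done)) break
    lo[hx < 0 & !done] <- x[hx < 0 & !done]
    hi[hx > 0 & !done] <- x[hx > 0 & !done]
    deriv <- hp(x)
    step <- ifelse(deriv > 0, hx / deriv, NA_real_)
    cand <- x - step
    # fall back to bisection when Newton leaves the bracket or stalls
    use_bis <- !is.finite(cand) | cand <= lo | cand >= hi
    cand[use_bis] <- (lo[use_bis] + hi[use_bis]) / 2
    step[use_bis] <- (hi[use_bis] - lo[use_bis]) / 2
    x <- ifelse(done, x, cand)
  }
  bad <- abs(h(x)) >= tol * (1 + abs(x)) & (hi - lo) > tol * (1 + abs(x))
  if (any(bad)) {
    stop("residence-time solver did not converge; worst residual ",
         format(max(abs(h(x)[bad]))), " after ", max_iter, " iterations",
         call. = FALSE)
  }
  # t = 0 must map exactly to T = 0
  x[t == 0] <- 0
  x
}

#' Net gain rate of a trip
#'
#' The simplified single-patch currency: gain divided by the total time
#' budget, \eqn{E_{net} = g(T) / (T - t)} with `t <= 0`, so the denominator is
#' residence time plus round-trip travel time. Maximised, for fixed `t`, at
#' the tangency point where it equals the marginal rate [gain_rate()].
#'
#' @inheritParams predict_travel_time
#' @param t Signed travel time in minutes (<= 0), vectorised.
#' @return Net gain rate (gain unit per minute).
#' @export
net_gain_rate <- function(curve, T, t) {
  check_curve(curve)
  if (any(T <= 0, na.rm = TRUE)) stop("residence time `T` must be > 0", call. = FALSE)
  if (any(t > 0, na.rm = TRUE)) stop("travel time `t` must be <= 0", call. = FALSE)
  denom <- T - t
  if (any(denom == 0, na.rm = TRUE)) stop("total time budget T - t must be non-zero", call. = FALSE)
  gain(curve, T) / denom
}

#' Tangent line to the gain curve
#'
#' Returns the tangent at \eqn{(T_0, g(T_0))}: slope \eqn{g'(T_0)} and
#' intercept \eqn{g(T_0) - g'(T_0) T_0}. Its zero crossing is the
#' MVT-optimal travel time for `T0` (see [predict_travel_time()]); because
#' the curve is concave the line lies on or above it everywhere.
#'
#' @inheritParams gain
#' @param T0 Tangency residence time in minutes (> 0), vectorised.
#' @return A [tibble::tibble] with columns `T0`, `slope`, `intercept`, and
#'   `zero_crossing` (the signed travel time where the line meets gain 0).
#' @export
tangent_line <- function(curve, T0) {
  check_curve(curve)
  if (any(T0 <= 0, na.rm = TRUE)) stop("`T0` must be > 0", call. = FALSE)
  slope <- gain_rate(curve, T0)
  intercept <- gain(curve, T0) - slope * T0
  tibble::tibble(
    T0 = T0,
    slope = slope,
    intercept = intercept,
    zero_crossing = -intercept / slope
  )
}
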