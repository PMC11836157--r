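#' Configuration for the synthetic survey generator
#'
#' Bundles every knob of [simulate_foragers()] into one validated list. The
#' generative model mirrors the analysis model: each simulated shopper draws a
#' true round-trip travel time, stays in the patch for the MVT-optimal
#' residence time implied by the common gain curve, obtains the curve's gain,
#' and then *reports* all three quantities with independent Gaussian error,
#' rounded to survey-style granularity. Contextual attributes (main patch,
#' trip type, transport mode, demographics) are drawn from independent
#' mixtures so the subset filters and clustering stages have material to work
#' on.
#'
#' @param A_true,k_true True gain-curve parameters (Euro; 1/minute).
#' @param n Number of records to generate.
#' @param travel_dist Distribution of the true round-trip travel time in
#'   minutes (positive): a list with `family` (currently `"lognormal"` or
#'   `"uniform"`), its parameters (`meanlog`/`sdlog` or `min`/`max`), and
#'   truncation bounds `lower`/`upper`. The default is log-normal with median
#'   8 min truncated to \[2, 20\] min, matching walking round-trips where
#'   reported totals stay under 20 minutes.
#' @param curve_shape `"exponential"` (the analysis model) or `"plateau"` (a
#'   linear-until-cutoff feedback curve, used to probe robustness of the
#'   exponential fit to a misspecified generator).
#' @param plateau_slope,plateau_T Parameters of the plateau shape (Euro/min;
#'   minutes). Ignored for the exponential shape.
#' @param plateau_jitter_sd SD (minutes) of the jitter added to the plateau
#'   corner when the plateau shape is generated: the tangent-optimal
#'   residence time for that shape is the corner itself for any travel time,
#'   so variation must come from behavioural noise.
#' @param sigma_T,sigma_t,sigma_g Reporting-error SDs for residence time
#'   (min), travel time (min) and gain (Euro). Zero switches the noise off.
#' @param round_T,round_t Rounding granularity of reported times (minutes;
#'   0 disables rounding).
#' @param round_g Rounding granularity of reported spend (Euro; 0 disables).
#' @param p_main_patch,p_home_roundtrip,p_foot Bernoulli probabilities of the
#'   three subset-filter attributes (shops mainly here; home-to-patch-and-back
#'   trip; travels by foot).
#' @param p_missing_key Probability that each of the three key fields (gain,
#'   travel time, residence time) is independently left blank, exercising the
#'   exclusion rule.
#' @param demographics A list of mixture specs for the contextual variables;
#'   see the default for the expected names.
#' @param seed Optional integer seed; when non-`NULL`, generation is
#'   reproducible and a given (config, seed) pair always yields an identical
#'   table.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(A_true = 60,
                       k_true = 0.08,
                       n = 61,
                       travel_dist = list(family = "lognormal",
                                          meanlog = log(8), sdlog = 0.5,
                                          lower = 2, upper = 20),
                       curve_shape = c("exponential", "plateau"),
                       plateau_slope = 4,
                       plateau_T = 15,
                       plateau_jitter_sd = 2,
                       sigma_T = 2,
                       sigma_t = 2,
                       sigma_g = 5,
                       round_T = 1,
                       round_t = 1,
                       round_g = 0.5,
                       p_main_patch = 0.8,
                       p_home_roundtrip = 0.65,
                       p_foot = 0.62,
                       p_missing_key = 0.02,
                       demographics = default_demographics(),
                       seed = NULL) {
  curve_shape <- match.arg(curve_shape)
  stopifnot(n >= 1, A_true > 0, k_true > 0,
            sigma_T >= 0, sigma_t >= 0, sigma_g >= 0,
            round_T >= 0, round_t >= 0, round_g >= 0)
  probs <- c(p_main_patch, p_home_roundtrip, p_foot, p_missing_key)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!is.list(travel_dist) || is.null(travel_dist$family)) {
    stop("`travel_dist` must be a list with a `family` element", call. = FALSE)
  }
  if (!travel_dist$family %in% c("lognormal", "uniform")) {
    stop("unsupported travel_dist family: ", travel_dist$family, call. = FALSE)
  }
  if (curve_shape == "plateau" && (plateau_slope <= 0 || plateau_T <= 0)) {
    stop("plateau parameters must be positive", call. = FALSE)
  }
  structure(
    list(A_true = A_true, k_true = k_true, n = as.integer(n),
         travel_dist = travel_dist, curve_shape = curve_shape,
         plateau_slope = plateau_slope, plateau_T = plateau_T,
         plateau_jitter_sd = plateau_jitter_sd,
         sigma_T = sigma_T, sigma_t = sigma_t, sigma_g = sigma_g,
         round_T = round_T, round_t = round_t, round_g = round_g,
         p_main_patch = p_main_patch, p_home_roundtrip = p_home_roundtrip,
         p_foot = p_foot, p_missing_key = p_missing_key,
         demographics = demographics, seed = seed),
    class = "sim_config")
}

#' Default demographic mixture for the generator
#'
#' Category frequencies follow the composition of a city-centre supermarket
#' sample: mostly one- and two-person households, walk-in shoppers of working
#' age with a long right tail, and a work-status mix dominated by students
#' and full-time employees.
#'
#' @return A list of mixture specifications consumed by [simulate_foragers()].
#' @export
default_demographics <- function() {
  list(
    age = list(mean = 35.5, sd = 15.9, min = 18, max = 90),
    gender = c(male = 0.575, female = 0.405, nonbinary = 0.015, agender = 0.005),
    work_status = c(student = 0.353, full_time = 0.347, part_time = 0.079,
                    retired = 0.074, pupil = 0.042, self_employed = 0.021,
                    trainee = 0.021, other = 0.063),
    household_n = c(`1` = 0.40, `2` = 0.40, `3` = 0.12, `4` = 0.06, `5` = 0.02),
    group_size = c(`1` = 0.75, `2` = 0.20, `3` = 0.05),
    shop_freq = c("less than once a week" = 0.10,
                  "once a week" = 0.20,
                  "twice a week" = 0.20,
                  "3 or 4 times a week" = 0.30,
                  "5 or 6 times a week" = 0.15,
                  "daily" = 0.05),
    p_exhausted = 0.3
  )
}

draw_travel_times <- function(spec, n) {
  lower <- spec$lower %||% 0
  upper <- spec$upper %||% Inf
  draw <- switch(spec$family,
    lognormal = function(m) stats::rlnorm(m, spec$meanlog, spec$sdlog),
    uniform   = function(m) stats::runif(m, spec$min, spec$max)
  )
  out <- numeric(0)
  # rejection sampling against the truncation bounds
  for (i in 1:1000) {
    need <- n - length(out)
    if (need <= 0) break
    x <- draw(max(need * 2L, 32L))
    out <- c(out, x[x >= lower & x <= upper])
  }
  if (length(out) < n) stop("travel-time truncation bounds reject too much mass", call. = FALSE)
  out[seq_len(n)]
}

round_to <- function(x, unit) {
  if (unit <= 0) return(x)
  round(x / unit) * unit
}

#' Piecewise linear-plateau gain curve
#'
#' The alternative feedback shape: gain accrues linearly at `slope` until the
#' patch's useful content is exhausted at `plateau_T`, then stays constant
#' (an empty-shelf plateau). Used only as a misspecified generator shape to
#' test how the exponential fit degrades; it is not a fitting model.
#'
#' @param slope Linear gain rate (Euro/min), > 0.
#' @param plateau_T Corner time in minutes, > 0.
#' @param T Residence times in minutes, >= 0; vectorised.
#' @return Gains in Euro: `slope * pmin(T, plateau_T)`.
#' @export
plateau_gain <- function(slope, plateau_T, T) {
  if (slope <= 0) stop("`slope` must be positive", call. = FALSE)
  if (plateau_T <= 0) stop("`plateau_T` must be positive", call. = FALSE)
  if (any(T < 0, na.rm = TRUE)) stop("`T` must be >= 0", call. = FALSE)
  slope * pmin(T, plateau_T)
}

#' Simulate survey-style forager records
#'
#' Generates a tibble of shopping-trip records with the statistical structure
#' the MVT analysis assumes: a common gain curve, optimal residence times
#' implied by each trip's travel time, and reporting error on both axes.
#' Reported times and spends are noisy, rounded versions of the latent truth,
#' floored at half a rounding unit so they stay positive; key fields are
#' blanked at random to exercise the exclusion rule downstream.
#'
#' The returned table also carries the latent truth (`t_true`, `T_true`,
#' `gain_true`) and a `complete_key` flag, plus an attribute `n_complete`
#' recording the generator's own count of records with all three key fields
#' present — useful for cross-checking exclusion bookkeeping.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per simulated trip. Reported columns are
#'   `travel_time_min` (positive round-trip minutes), `patch_time_min`,
#'   `gain_euro`, `n_products`, the filter flags `main_patch`, `trip_type`,
#'   `transport`, and the demographic fields `shop_freq_raw`, `household_n`,
#'   `group_size`, `age`, `gender`, `work_status`, `exhaustion`.
#' @examples
#' recs <- simulate_foragers(sim_config(n = 20, seed = 1))
#' dplyr::glimpse(recs)
#' @export
simulate_foragers <- function(config) {
  if (!inherits(config, "sim_config")) stop("`config` must come from sim_config()", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  dem <- config$demographics

  t_true <- draw_travel_times(config$travel_dist, n)          # positive minutes
  if (config$curve_shape == "exponential") {
    curve <- gain_curve(config$A_true, config$k_true)
    T_true <- solve_residence_time(curve, -t_true)
    g_true <- gain(curve, T_true)
  } else {
    # the tangent-optimal residence time for a linear-plateau curve is the
    # corner itself for every travel time; variation is behavioural jitter
    T_true <- pmax(1, config$plateau_T +
                     stats::rnorm(n, 0, config$plateau_jitter_sd))
    g_true <- plateau_gain(config$plateau_slope, config$plateau_T, T_true)
  }

  report <- function(x, sigma, unit) {
    y <- x + stats::rnorm(n, 0, sigma)
    y <- round_to(y, unit)
    floor_at <- if (unit > 0) unit / 2 else 0.25
    pmax(y, floor_at)
  }
  patch_time <- report(T_true, config$sigma_T, config$round_T)
  travel_time <- report(t_true, config$sigma_t, config$round_t)
  gain_rep <- report(g_true, config$sigma_g, config$round_g)
  # product count: a coarse integer re-expression of the same latent gain
  n_products <- 1L + stats::rpois(n, pmax(g_true, 0) / 2.5)

  cat_draw <- function(p, m = n) sample(names(p), m, replace = TRUE, prob = p)
  age <- round(pmin(dem$age$max, pmax(dem$age$min,
                stats::rnorm(n, dem$age$mean, dem$age$sd))))

  miss <- function() stats::runif(n) < config$p_missing_key
  gain_rep[miss()] <- NA_real_
  travel_time[miss()] <- NA_real_
  patch_time[miss()] <- NA_real_

  out <- tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    travel_time_min = travel_time,
    patch_time_min = patch_time,
    gain_euro = gain_rep,
    n_products = n_products,
    main_patch = stats::runif(n) < config$p_main_patch,
    trip_type = ifelse(stats::runif(n) < config$p_home_roundtrip,
                       "home_roundtrip",
                       sample(c("en_route", "other"), n, replace = TRUE)),
    transport = ifelse(stats::runif(n) < config$p_foot, "foot",
                       sample(c("bike", "car", "public"), n, replace = TRUE)),
    shop_freq_raw = cat_draw(dem$shop_freq),
    household_n = as.integer(cat_draw(dem$household_n)),
    group_size = as.integer(cat_draw(dem$group_size)),
    age = age,
    gender = cat_draw(dem$gender),
    work_status = cat_draw(dem$work_status),
    exhaustion = stats::runif(n) < dem$p_exhausted,
    t_true = t_true,
    T_true = T_true,
    gain_true = g_true
  )
  out$complete_key <- stats::complete.cases(
    out[, c("gain_euro", "travel_time_min", "patch_time_min")])
  attr(out, "n_complete") <- sum(out$complete_key)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
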