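#' Run the full MVT survey analysis pipeline
#'
#' End-to-end orchestration: exclusion of incomplete records, selection of
#' the applicability subset, categorisation, the two exploratory cluster
#' analyses with elbow selection, the orthogonal-distance fit of the gain
#' curve, residual diagnostics, travel-time evaluation, and the exploratory
#' Welch tests (gender, and a median split on age). Input is either a data
#' frame of records, a survey CSV path, or a [sim_config()] to simulate
#' from; exactly one must be supplied. The same seed and input always
#' produce an identical summary.
#'
#' @param records A data frame of forager records (e.g. from
#'   [simulate_foragers()] or [read_survey()]).
#' @param csv Path to a survey CSV, read with [read_survey()].
#' @param config A [sim_config()] to generate synthetic records from.
#' @param gain_unit `"euro"` (spend, default) or `"n_products"`: which gain
#'   operationalisation enters the fit.
#' @param apply_filters Apply the three subset filters (main patch, home
#'   round trip, by foot)? `FALSE` fits on all complete records.
#' @param cluster Run the two exploratory cluster analyses? Default `TRUE`.
#' @param k_max Largest cluster count considered by [scree_elbow()].
#' @param seed Integer seed controlling simulation (when `config` lacks one)
#'   and any other randomness; recorded in the summary.
#' @return A list of class `mvt_pipeline` with elements `records`,
#'   `exclusion` (kept/excluded row counts), `subset_report`, `subset`,
#'   `clustering` (socioeconomic Jaccard and numeric Euclidean analyses),
#'   `fit` (`odr_fit`), `diagnostics`, `travel` (`travel_eval`),
#'   `welch` (gender and age-group tests on residence time), and `summary`,
#'   a flat named list of the headline numbers.
#' @examples
#' run <- run_mvt_pipeline(config = sim_config(n = 120, seed = 7))
#' run$summary$subset_n
#' @export
run_mvt_pipeline <- function(records = NULL, csv = NULL, config = NULL,
                             gain_unit = c("euro", "n_products"),
                             apply_filters = TRUE, cluster = TRUE,
                             k_max = 10, seed = NULL) {
  gain_unit <- match.arg(gain_unit)
  sources <- sum(!is.null(records), !is.null(csv), !is.null(config))
  if (sources != 1) {
    stop("supply exactly one of `records`, `csv`, `config`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(config)) {
    if (is.null(config$seed) && !is.null(seed)) config$seed <- seed
    records <- simulate_foragers(config)
  }
  if (!is.null(csv)) records <- read_survey(csv)
  records <- tibble::as_tibble(records)

  excl <- exclude_incomplete(records)
  kept <- categorize(excl$kept)

  clustering <- NULL
  if (cluster && nrow(kept) >= 4) {
    dummy_cols <- grep("^dummy_", names(kept), value = TRUE)
    dummies <- kept[dummy_cols]
    dummies <- dummies[, colSums(is.na(dummies)) == 0, drop = FALSE]
    socio <- NULL
    if (ncol(dummies) >= 2) {
      hc_j <- cluster_complete(jaccard_distance_matrix(dummies))
      socio <- list(hclust = hc_j, elbow = scree_elbow(hc_j, k_max))
    }
    num <- kept[c("travel_time_min", "patch_time_min", "gain_euro")]
    hc_e <- cluster_complete(euclidean_distance_matrix(num))
    clustering <- list(socioeconomic = socio,
                       numeric = list(hclust = hc_e,
                                      elbow = scree_elbow(hc_e, k_max)))
  }

  if (apply_filters) {
    sel <- select_mvt_subset(kept)
    subset <- sel$subset
    subset_report <- sel$report
  } else {
    subset <- kept
    subset_report <- tibble::tibble(step = "none", n_before = nrow(kept),
                                    n_dropped = 0L, n_after = nrow(kept))
  }
  if (nrow(subset) < 3) {
    return(structure(list(
      records = records,
      exclusion = list(n_input = nrow(records), n_excluded = nrow(excl$excluded)),
      subset_report = subset_report, subset = subset,
      clustering = clustering, fit = NULL, diagnostics = NULL, travel = NULL,
      welch = NULL,
      summary = list(n_input = nrow(records), subset_n = nrow(subset),
                     error = "subset too small to fit")
    ), class = "mvt_pipeline"))
  }

  gain_col <- if (gain_unit == "euro") "gain_euro" else "n_products"
  fit <- fit_gain_odr(subset, time = "patch_time_min", gain = gain_col)
  diagnostics <- diagnose_fit(fit)
  travel <- evaluate_travel_predictions(fit, subset)

  welch <- list()
  if ("gender" %in% names(subset)) {
    g <- subset$gender
    a <- subset$patch_time_min[g %in% "male"]
    b <- subset$patch_time_min[g %in% "female"]
    if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2) {
      welch$gender <- welch_t_test(a, b)
    }
  }
  if ("age" %in% names(subset) && sum(!is.na(subset$age)) >= 4) {
    grp <- median_split(subset$age)
    a <- subset$patch_time_min[grp %in% "low"]
    b <- subset$patch_time_min[grp %in% "high"]
    if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2) {
      welch$age <- welch_t_test(a, b)
    }
  }

  summary <- list(
    seed = seed,
    n_input = nrow(records),
    n_excluded_incomplete = nrow(excl$excluded),
    subset_n = nrow(subset),
    gain_unit = gain_unit,
    A_hat = fit$A_hat,
    k_hat = fit$k_hat,
    se_resid_gain = fit$se,
    s2_resid_gain = fit$s2,
    paired_t_gain = diagnostics$paired_t$t,
    paired_p_gain = diagnostics$paired_t$p,
    bias_intercept = diagnostics$bias$intercept,
    bias_slope = diagnostics$bias$slope,
    se_resid_travel = travel$se,
    s2_resid_travel = travel$s2,
    paired_t_travel = travel$paired_t$t,
    paired_p_travel = travel$paired_t$p,
    welch_t_gender = if (!is.null(welch$gender)) welch$gender$t else NA_real_,
    welch_t_age = if (!is.null(welch$age)) welch$age$t else NA_real_,
    elbow_k_numeric = if (!is.null(clustering)) clustering$numeric$elbow$k else NA_integer_,
    elbow_k_socioeconomic = if (!is.null(clustering) && !is.null(clustering$socioeconomic))
      clustering$socioeconomic$elbow$k else NA_integer_
  )

  structure(list(
    records = records,
    exclusion = list(n_input = nrow(records), n_excluded = nrow(excl$excluded)),
    subset_report = subset_report, subset = subset,
    clustering = clustering, fit = fit, diagnostics = diagnostics,
    travel = travel, welch = welch, summary = summary
  ), class = "mvt_pipeline")
}

#' @export
print.mvt_pipeline <- function(x, ...) {
  s <- x$summary
  cat("MVT survey pipeline run\n")
  cat(sprintf("  records: %d in, %d excluded incomplete, subset n = %d\n",
              s$n_input, s$n_excluded_incomplete %||% NA, s$subset_n))
  if (!is.null(x$fit)) {
    cat(sprintf("  gain fit: A_hat = %.3f, k_hat = %.4f, se_resid = %.3f\n",
                s$A_hat, s$k_hat, s$se_resid_gain))
    cat(sprintf("  travel:   se_resid = %.3f, paired t = %.3f (p = %.3f)\n",
                s$se_resid_travel, s$paired_t_travel, s$paired_p_travel))
  } else {
    cat("  fit not run: ", s$error %||% "", "\n")
  }
  invisible(x)
}

#' Write a pipeline bundle to disk
#'
#' Serialises the machine-readable pieces of a [run_mvt_pipeline()] result:
#' `summary.json`, `subset_report.csv`, the subset records, per-record fit
#' and travel residual tables, and the scree series.
#'
#' @param run An `mvt_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_bundle <- function(run, dir) {
  if (!inherits(run, "mvt_pipeline")) stop("`run` must be an mvt_pipeline", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_csv(run$subset_report, file.path(dir, "subset_report.csv"))
  write_survey(run$subset, file.path(dir, "subset.csv"))
  if (!is.null(run$fit)) {
    readr::write_csv(augment(run$fit), file.path(dir, "gain_residuals.csv"))
    readr::write_csv(augment(run$travel), file.path(dir, "travel_residuals.csv"))
  }
  if (!is.null(run$clustering)) {
    readr::write_csv(run$clustering$numeric$elbow$scree,
                     file.path(dir, "scree_numeric.csv"))
  }
  invisible(dir)
}
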