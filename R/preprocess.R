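#' Read a forager survey CSV
#'
#' Reads a comma-separated survey table (UTF-8, header row, decimal point,
#' empty string = missing) into a typed tibble. The three key analysis
#' columns `travel_time_min`, `patch_time_min` and `gain_euro` are mandatory;
#' unknown columns are preserved untouched. An `estimated_distance_km`
#' column, if present, is dropped before analysis (self-reported distances
#' are not used).
#'
#' @param path Path to a CSV file.
#' @return A tibble of forager records. Cells that fail numeric parsing are
#'   reported with their row indices via a warning and become `NA`.
#' @export
read_survey <- function(path) {
  mandatory <- c("travel_time_min", "patch_time_min", "gain_euro")
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  absent <- setdiff(mandatory, header)
  if (length(absent) > 0) {
    stop("survey file is missing mandatory column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- intersect(
    c("travel_time_min", "patch_time_min", "gain_euro", "n_products",
      "household_n", "group_size", "age", "t_true", "T_true", "gain_true"),
    header)
  logical_cols <- intersect(c("main_patch", "exhaustion", "complete_key"), header)
  spec <- readr::cols(.default = readr::col_character())
  for (cc in numeric_cols) spec$cols[[cc]] <- readr::col_double()
  for (cc in logical_cols) spec$cols[[cc]] <- readr::col_logical()
  out <- suppressWarnings(readr::read_csv(path, col_types = spec,
                                          na = c("", "NA"),
                                          show_col_types = FALSE))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    warning("malformed cells in ", path, " at row(s) ",
            paste(unique(probs$row), collapse = ", "),
            "; values set to NA", call. = FALSE)
  }
  out$estimated_distance_km <- NULL
  out
}

#' Write forager records to CSV
#'
#' Companion to [read_survey()]: UTF-8, comma-separated, header row, empty
#' string for missing values.
#'
#' @param records A tibble of forager records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Exclude records with a missing key field
#'
#' A record enters the analysis only if gain, travel time and patch residence
#' time are all reported; any blank among the three excludes it. The split is
#' exhaustive and disjoint, so exclusion bookkeeping always sums.
#'
#' @param records A tibble with columns `gain_euro`, `travel_time_min`,
#'   `patch_time_min`.
#' @return A list with tibbles `kept` and `excluded`.
#' @export
exclude_incomplete <- function(records) {
  need <- c("gain_euro", "travel_time_min", "patch_time_min")
  absent <- setdiff(need, names(records))
  if (length(absent) > 0) {
    stop("records lack key column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  ok <- stats::complete.cases(records[, need])
  list(kept = records[ok, , drop = FALSE],
       excluded = records[!ok, , drop = FALSE])
}

#' Select the subset in which the MVT model is cleanly applicable
#'
#' Keeps records of shoppers who (a) mainly shop at the surveyed supermarket
#' (so they know the patch's profitability), (b) travelled from home to the
#' patch and back (so the whole round trip is attributable travel cost), and
#' (c) travelled by foot (so effort is roughly proportional to time). Filters
#' are applied in the fixed order a, b, c purely so the attrition report is
#' reproducible; the final subset is order-independent.
#'
#' @param records A tibble with columns `main_patch`, `trip_type`,
#'   `transport` (records should already have passed [exclude_incomplete()]).
#' @return A list with `subset` (tibble) and `report`, a tibble of per-filter
#'   attrition: columns `step`, `n_before`, `n_dropped`, `n_after`.
#' @export
select_mvt_subset <- function(records) {
  steps <- list(
    main_patch     = function(d) !is.na(d$main_patch) & d$main_patch,
    home_roundtrip = function(d) !is.na(d$trip_type) & d$trip_type == "home_roundtrip",
    by_foot        = function(d) !is.na(d$transport) & d$transport == "foot"
  )
  report <- tibble::tibble(step = character(), n_before = integer(),
                           n_dropped = integer(), n_after = integer())
  current <- records
  for (nm in names(steps)) {
    keep <- steps[[nm]](current)
    report <- dplyr::bind_rows(report, tibble::tibble(
      step = nm, n_before = nrow(current),
      n_dropped = sum(!keep), n_after = sum(keep)))
    current <- current[keep, , drop = FALSE]
  }
  list(subset = current, report = report)
}

# parser table for free-form shopping-frequency reports -> times per week
parse_shop_freq <- function(x) {
  x0 <- stringr::str_to_lower(trimws(x))
  x0 <- stringr::str_replace_all(x0, c("once" = "1", "twice" = "2",
                                       "three" = "3", "four" = "4",
                                       "five" = "5", "six" = "6",
                                       "seven" = "7"))
  per_week <- rep(NA_real_, length(x0))
  per_week[stringr::str_detect(x0, "daily|every day")] <- 7
  less <- stringr::str_detect(x0, "less|rare|month|seldom|fortnight")
  per_week[less] <- 0.5
  # "3 or 4 times a week", "3-4", "3 to 4": take the midpoint of the range
  rng <- stringr::str_match(x0, "(\\d+)\\s*(?:or|-|to|/)\\s*(\\d+)")
  has_rng <- !is.na(rng[, 1]) & is.na(per_week)
  per_week[has_rng] <- (as.numeric(rng[has_rng, 2]) + as.numeric(rng[has_rng, 3])) / 2
  single <- stringr::str_match(x0, "(\\d+(?:\\.\\d+)?)")
  has_single <- !is.na(single[, 1]) & is.na(per_week)
  per_week[has_single] <- as.numeric(single[has_single, 2])
  per_week
}

freq_bins <- c("<1/wk", "1-2/wk", "3-4/wk", "5+/wk")

#' Add analysis categories and dummy variables
#'
#' Builds the categorical variables used for clustering and group tests:
#' shopping frequency is parsed from the free-form report and binned into
#' `<1/wk`, `1-2/wk`, `3-4/wk`, `5+/wk` (range answers such as "3 or 4 times
#' a week" take the midpoint); household size is binned into `1`, `2`, `>2`;
#' age into `18-29`, `30-49`, `50+`. Each categorical variable — including
#' gender, work status, trip type, transport and the logical flags — is
#' expanded into 0/1 dummy columns (prefix `dummy_`); a missing source value
#' yields missing dummies. Unparseable frequency strings are reported via a
#' warning and treated as missing.
#'
#' @param records A tibble of forager records.
#' @return The input tibble with added columns `shop_freq_per_week`,
#'   `shop_freq_cat`, `household_cat`, `age_cat` and the dummy columns.
#' @export
categorize <- function(records) {
  out <- records
  if ("shop_freq_raw" %in% names(out)) {
    pw <- parse_shop_freq(out$shop_freq_raw)
    bad <- !is.na(out$shop_freq_raw) & is.na(pw)
    if (any(bad)) {
      warning("unparseable shopping-frequency report(s): ",
              paste(unique(out$shop_freq_raw[bad]), collapse = "; "),
              " — treated as missing", call. = FALSE)
    }
    out$shop_freq_per_week <- pw
    out$shop_freq_cat <- cut(pw, breaks = c(-Inf, 0.99, 2.5, 4.5, Inf),
                             labels = freq_bins)
  }
  if ("household_n" %in% names(out)) {
    out$household_cat <- cut(out$household_n, breaks = c(-Inf, 1, 2, Inf),
                             labels = c("1", "2", ">2"))
  }
  if ("age" %in% names(out)) {
    out$age_cat <- cut(out$age, breaks = c(-Inf, 29, 49, Inf),
                       labels = c("18-29", "30-49", "50+"))
  }
  cat_vars <- intersect(
    c("shop_freq_cat", "household_cat", "age_cat", "gender", "work_status",
      "trip_type", "transport"), names(out))
  flag_vars <- intersect(c("main_patch", "exhaustion"), names(out))
  for (v in cat_vars) {
    vals <- as.factor(out[[v]])
    for (lev in levels(vals)) {
      col <- paste0("dummy_", v, "_", make.names(lev))
      out[[col]] <- as.integer(vals == lev)
    }
  }
  for (v in flag_vars) {
    out[[paste0("dummy_", v)]] <- as.integer(out[[v]])
  }
  out
}

#' Median split of a numeric variable
#'
#' Dichotomises at the sample median: values at or below the median are
#' labelled `"low"`, values above `"high"`; missing values stay unlabelled.
#' Ties at the median go to the low group.
#'
#' @param values Numeric vector with at least two non-missing values.
#' @return A factor with levels `low`, `high` (NA where `values` is NA).
#' @export
median_split <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("median split needs at least 2 non-missing values", call. = FALSE)
  med <- stats::median(values[ok])
  factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
}
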