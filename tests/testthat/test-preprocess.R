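test_that("survey CSV round-trips through write and read", {
  recs <- simulate_foragers(sim_config(n = 30, p_missing_key = 0.1, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(recs, path)
  back <- read_survey(path)
  expect_equal(back$gain_euro, recs$gain_euro)
  expect_equal(back$travel_time_min, recs$travel_time_min)
  expect_equal(back$trip_type, recs$trip_type)
  expect_equal(back$main_patch, recs$main_patch)
  expect_equal(nrow(back), nrow(recs))
})

test_that("blank and malformed cells are handled at read time", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("travel_time_min,patch_time_min,gain_euro",
               "10,12,25.5",
               "8,,14",
               "7,9,abc"), path)
  expect_warning(d <- read_survey(path), "row")
  expect_true(is.na(d$patch_time_min[2]))
  expect_true(is.na(d$gain_euro[3]))

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("travel_time_min,gain_euro\n1,2", path2)
  expect_error(read_survey(path2), "patch_time_min")
})

test_that("records missing any key field are excluded, none else", {
  # survey-shaped fixture: 194 rows, 4 with a missing key field
  recs <- simulate_foragers(sim_config(n = 194, p_missing_key = 0, seed = 30))
  recs$gain_euro[c(3, 57)] <- NA
  recs$travel_time_min[101] <- NA
  recs$patch_time_min[180] <- NA
  split <- exclude_incomplete(recs)
  expect_equal(nrow(split$kept), 190)
  expect_equal(nrow(split$excluded), 4)
  expect_equal(nrow(split$kept) + nrow(split$excluded), nrow(recs))
  # idempotent
  again <- exclude_incomplete(split$kept)
  expect_equal(nrow(again$excluded), 0)
  expect_equal(again$kept, split$kept)
})

test_that("subset selection equals the brute-force conjunction with full attrition", {
  recs <- simulate_foragers(sim_config(n = 300, p_missing_key = 0, seed = 31))
  sel <- select_mvt_subset(recs)
  manual <- recs[recs$main_patch & recs$trip_type == "home_roundtrip" &
                   recs$transport == "foot", ]
  expect_equal(sel$subset, manual)
  expect_equal(sel$report$n_before[1], nrow(recs))
  expect_equal(sel$report$n_after[3], nrow(manual))
  # every row lands in exactly one attrition bucket
  expect_equal(sum(sel$report$n_dropped) + nrow(sel$subset), nrow(recs))
  # filtering is idempotent
  again <- select_mvt_subset(sel$subset)
  expect_equal(again$subset, sel$subset)
  expect_equal(sum(again$report$n_dropped), 0)
  # all-false flags give an empty subset
  recs2 <- recs
  recs2$main_patch <- FALSE
  expect_equal(nrow(select_mvt_subset(recs2)$subset), 0)
})

test_that("categorisation bins frequency, household size and age as documented", {
  d <- tibble::tibble(
    shop_freq_raw = c("3 or 4 times a week", "once a week", "daily",
                      "less than once a week", "5 or 6 times a week",
                      "twice a week", NA),
    household_n = c(1L, 2L, 4L, 3L, 1L, 2L, NA),
    age = c(22, 35, 67, 49, 29, 50, NA),
    gender = c("male", "female", "male", "female", "male", "female", "male")
  )
  out <- categorize(d)
  expect_equal(as.character(out$shop_freq_cat),
               c("3-4/wk", "1-2/wk", "5+/wk", "<1/wk", "5+/wk", "1-2/wk", NA))
  expect_equal(as.character(out$household_cat),
               c("1", "2", ">2", ">2", "1", "2", NA))
  expect_equal(as.character(out$age_cat),
               c("18-29", "30-49", "50+", "30-49", "18-29", "50+", NA))

  # dummies partition: rows with a non-missing source sum to exactly 1
  for (v in c("shop_freq_cat", "household_cat", "age_cat", "gender")) {
    cols <- grep(paste0("^dummy_", v), names(out), value = TRUE)
    sums <- rowSums(out[cols])
    expect_equal(sums[!is.na(out[[v]])], rep(1, sum(!is.na(out[[v]]))),
                 ignore_attr = TRUE)
    expect_true(all(is.na(sums[is.na(out[[v]])])))
  }

  expect_warning(categorize(tibble::tibble(shop_freq_raw = "whenever")),
                 "unparseable")
})

test_that("median split labels low at or below the median", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(median_split(c(5, 5, 5))), rep("low", 3))
  expect_error(median_split(c(NA, NA, 1)), "2 non-missing")
  set.seed(2)
  x <- sample(1:20, 101, replace = TRUE)
  lab <- median_split(x)
  ties <- sum(x == stats::median(x))
  expect_lte(abs(sum(lab == "low") - sum(lab == "high")), ties)
})
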