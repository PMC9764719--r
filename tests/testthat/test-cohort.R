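test_that("inclusion filters drop pre-year and end-of-year admissions", {
  rec <- make_records(admission_day = c(0, 1, 200, 351, 352),
                      discharge_day = c(5, 4, 205, 355, 360))
  out <- suppressMessages(apply_inclusion_filters(rec, 365))
  expect_identical(sort(out$admission_day), c(1L, 200L, 351L))
  excl <- attr(out, "exclusions")
  expect_identical(unname(excl["admitted_before_study_year"]), 1L)
  expect_identical(unname(excl["admitted_in_final_two_weeks"]), 1L)

  empty <- make_records(integer(0), integer(0))
  expect_identical(nrow(suppressMessages(apply_inclusion_filters(empty))), 0L)
})

test_that("record validation catches malformed rows", {
  bad <- make_records(5, 3)
  expect_error(validate_records(bad), class = "occmsm_validation_error")
  bad <- make_records(1, 5); bad$pccl <- 7L
  expect_error(validate_records(bad), class = "occmsm_validation_error")
  bad <- make_records(1, 5, died = TRUE, death_day = 9)
  expect_error(validate_records(bad), class = "occmsm_validation_error")
  # discharge on the death day is normalized so the death day is a bed day
  ok <- validate_records(make_records(1, 3, died = TRUE, death_day = 3))
  expect_identical(ok$last_present, 3L)
})

test_that("census, utilization and turnover match the hand-enumerated toy ward", {
  # P1 in house days 1-2, P2 same-day stay on day 2, P3 in house days 2-4
  rec <- make_records(admission_day = c(1, 2, 2),
                      discharge_day = c(3, 2, 5))
  hd <- build_daily_series(rec, year_length = 5)
  expect_identical(hd$census, c(1L, 3L, 1L, 1L, 0L))
  expect_equal(hd$cu, 100 * c(1, 3, 1, 1, 0) / 3)
  # day 2: two admissions plus the same-day discharge over the peak of 3
  expect_equal(hd$turnover[2], 100 * (2 + 1) / 3)
  expect_true(is.na(hd$mean_pccl[5]))
  # conservation: census-days equal patient days present
  expect_identical(sum(hd$census), 2L + 1L + 3L)
})

test_that("a patient in house all year gives constant full utilization", {
  rec <- make_records(1, 400)
  hd <- build_daily_series(rec, year_length = 365)
  expect_true(all(hd$cu == 100))
})

test_that("thresholds follow the interpolated sample quantile with ties exposed", {
  hd <- data.frame(hospital_id = 1L, cu = 1:20)
  thr <- derive_threshold(hd, 85)
  expect_equal(thr$threshold, 17.15)
  expect_identical(sum(hd$cu >= thr$threshold), 3L)

  const <- data.frame(hospital_id = 1L, cu = rep(7, 10))
  thr <- derive_threshold(const, 85)
  expect_equal(thr$threshold, 7)
  expect_true(all(const$cu >= thr$threshold))

  two <- data.frame(hospital_id = 1L, cu = c(10, 90))
  expect_equal(derive_threshold(two, 85)$threshold, 78)

  expect_error(derive_threshold(data.frame(hospital_id = 1L, cu = NA_real_),
                                85),
               class = "occmsm_validation_error")
  expect_error(derive_threshold(hd, 0), class = "occmsm_config_error")
})

toy_hd <- function(exposed_days, year_length = 40L) {
  # one hospital whose high-occupancy days are exactly `exposed_days`
  cu <- rep(50, year_length)
  cu[exposed_days] <- 100
  data.frame(hospital_id = 1L, day = seq_len(year_length), census = 10L,
             admissions = 0L, discharges = 0L, cu = cu, turnover = 20,
             mean_pccl = 1.0, is_weekend = FALSE)
}

test_that("person-day expansion censors at discharge, death and day 14", {
  hd <- toy_hd(c(1, 3))
  thr <- data.frame(hospital_id = 1L, percentile = 85, threshold = 100)

  alive1 <- make_records(1, 2)  # one day in house
  pd <- expand_person_days(alive1, hd, thr)
  expect_identical(nrow(pd), 1L)
  expect_identical(pd$t, 1L)
  expect_identical(pd$Y, 0L)

  died3 <- make_records(1, 10, died = TRUE, death_day = 3)
  pd <- expand_person_days(died3, hd, thr)
  expect_identical(pd$A, c(1L, 0L, 1L))
  expect_identical(pd$cumA, c(1L, 1L, 2L))
  expect_identical(pd$Y, c(0L, 0L, 1L))
  # lagged history used by the exposure models
  expect_identical(pd$A_lag, c(0L, 1L, 0L))
  expect_identical(pd$cumA_lag, c(0L, 1L, 1L))

  long <- make_records(1, 21)  # twenty days in house, capped at 14
  expect_identical(nrow(expand_person_days(long, hd, thr)), 14L)

  # lagged cumulative exposure convention drops the current day
  pd_lag <- expand_person_days(died3, hd, thr, exposure_lag = TRUE)
  expect_identical(pd_lag$cumA, c(0L, 1L, 1L))
})

test_that("person-day rows match a brute-force per-patient loop", {
  cfg <- tiny_sim(seed = 3)
  parts <- cohort_persondays(cfg)
  pd <- parts$persondays
  rec <- parts$records
  expected <- sum(pmin(rec$last_present - rec$admission_day + 1L, 14L))
  expect_identical(nrow(pd), expected)
  # cumulative exposure is non-decreasing and binary exposure is 0/1
  expect_true(all(pd$A %in% c(0L, 1L)))
  expect_true(all(pd[, all(diff(cumA) >= 0), by = patient_id]$V1))
  # deaths in the person-day table equal 14-day deaths in the cohort
  d14 <- rec$died & (rec$death_day - rec$admission_day + 1L) <= 14L
  expect_identical(sum(pd$Y), sum(d14))
})

test_that("unfiltered cohorts cannot be expanded past the year end", {
  hd <- toy_hd(1, year_length = 20L)
  thr <- data.frame(hospital_id = 1L, percentile = 85, threshold = 100)
  rec <- make_records(15, 40)  # runs past the available series
  expect_error(expand_person_days(rec, hd, thr),
               class = "occmsm_validation_error")
})

test_that("per-hospital exposed fraction sits at the percentile plus tie mass", {
  parts <- cohort_persondays(tiny_sim(seed = 9))
  fl <- flag_exposure(parts$hospital_days, parts$thresholds)
  byh <- fl[, .(frac = mean(exposed),
                tie = mean(cu == threshold)), by = hospital_id]
  n_days <- 120
  expect_true(all(byh$frac >= 0.15 - 1 / n_days - 1e-9))
  expect_true(all(byh$frac <= 0.15 + byh$tie + 1 / n_days + 1e-9))
})

test_that("episode CSVs with ISO dates load through the documented contract", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,hospital_id,hospital_type,admission_date,discharge_date,died,death_date,sex,age_group,pccl,elixhauser_weight",
    "1,1,2,2016-01-05,2016-01-10,FALSE,,female,10,2,0.5",
    "2,1,2,2016-01-09,2016-01-11,TRUE,2016-01-11,male,15,4,6.1"
  ), path)
  rec <- read_patient_records(path, year_start = "2016-01-01")
  expect_identical(rec$admission_day, c(5L, 9L))
  expect_identical(rec$discharge_day, c(10L, 12L))  # death day becomes a bed day
  expect_identical(rec$death_day, c(NA_integer_, 11L))
  # 2016-01-09 was a Saturday
  expect_identical(rec$weekend_admission, c(FALSE, TRUE))

  writeLines(c(
    "patient_id,hospital_id,hospital_type,admission_date,discharge_date,died,death_date,sex,age_group,pccl,elixhauser_weight",
    "1,1,2,not-a-date,2016-01-10,FALSE,,female,10,2,0.5"), path)
  expect_error(read_patient_records(path, year_start = "2016-01-01"),
               class = "occmsm_validation_error")
})
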