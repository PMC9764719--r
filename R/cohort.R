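# Cohort derivation: episode validation and inclusion filters, per-hospital
# daily series (census, capacity utilization, turnover, mean complexity),
# hospital-specific percentile thresholds, and the censored 14-day person-day
# table used by the weighting and outcome models.

record_columns <- c("patient_id", "hospital_id", "hospital_type",
                    "admission_day", "discharge_day", "died", "death_day",
                    "sex", "age_group", "pccl", "elixhauser_weight",
                    "weekend_admission")

#' Validate and normalize patient-level episode records
#'
#' Checks the episode-table contract (one row per hospital episode) and
#' normalizes the discharge convention: a patient occupies a bed on the days
#' `[admission_day, discharge_day)`, same-day stays count as present on the
#' admission day, and a death day is always a bed day (records whose discharge
#' day equals the death day are shifted so the bed is freed the following
#' day). Adds the `last_present` helper column used by the census and
#' person-day builders.
#'
#' @param records A data.frame with columns `patient_id`, `hospital_id`,
#'   `hospital_type` (1-5), `admission_day`, `discharge_day` (integer day of
#'   study year), `died` (logical), `death_day` (`NA` unless died), `sex`
#'   (`"female"`/`"male"`), `age_group` (5-year band index), `pccl` (0-4),
#'   `elixhauser_weight` (numeric), `weekend_admission` (logical).
#' @return A `data.table` with validated columns plus `last_present`.
#' @export
validate_records <- function(records) {
  rec <- if (is.data.table(records)) copy(records) else as.data.table(records)
  missing_cols <- setdiff(record_columns, names(rec))
  if (length(missing_cols))
    validation_error(paste("records missing columns:",
                           paste(missing_cols, collapse = ", ")))
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      validation_error(sprintf("row %d: %s", idx[1], what))
  }
  bad_row(!is.finite(rec$admission_day) | !is.finite(rec$discharge_day),
          "unparseable admission/discharge day")
  bad_row(rec$discharge_day < rec$admission_day,
          "discharge before admission")
  bad_row(!(rec$pccl %in% 0:4), "pccl outside 0-4")
  bad_row(rec$died & is.na(rec$death_day), "died without a death day")
  bad_row(rec$died & !is.na(rec$death_day) &
            (rec$death_day < rec$admission_day |
               rec$death_day > rec$discharge_day),
          "death day outside the stay")
  rec[, admission_day := as.integer(admission_day)]
  rec[, discharge_day := as.integer(discharge_day)]
  # a death day is a bed day: free the bed the day after death
  rec[died == TRUE & discharge_day == death_day,
      discharge_day := discharge_day + 1L]
  rec[, last_present := fifelse(died & !is.na(death_day),
                                as.integer(death_day),
                                pmax(admission_day, discharge_day - 1L))]
  rec[]
}

#' Apply study inclusion filters
#'
#' Drops episodes admitted before the study year (admission day < 1) and
#' episodes admitted within the final two weeks of the year (admission day
#' greater than `year_length - 14`), so every retained patient has a complete
#' 14-day exposure and outcome window inside the year. The number of episodes
#' dropped by each rule is attached as the `"exclusions"` attribute and
#' reported via [message()].
#'
#' @param records Episode table (see [validate_records()]).
#' @param year_length Length of the study year in days.
#' @param quiet Suppress the exclusion-count message?
#' @return Filtered `data.table` with attribute `exclusions`.
#' @export
apply_inclusion_filters <- function(records, year_length = 365L, quiet = FALSE) {
  rec <- validate_records(records)
  before_year <- rec$admission_day < 1L
  last_two_weeks <- !before_year & rec$admission_day > (year_length - 14L)
  out <- rec[!(before_year | last_two_weeks)]
  excl <- c(admitted_before_study_year = sum(before_year),
            admitted_in_final_two_weeks = sum(last_two_weeks))
  if (!quiet)
    message(sprintf(
      "inclusion filters: dropped %d admitted before the study year, %d admitted in the final two weeks; %d episodes retained",
      excl[1], excl[2], nrow(out)))
  setattr(out, "exclusions", excl)
  out
}

#' Derive per-hospital daily series
#'
#' Computes, for every hospital and study-year day: the in-house census (bed
#' occupancy) under the half-open stay convention, admission and discharge
#' counts, capacity utilization `cu` (census as a percentage of that
#' hospital's peak day), patient turnover (admissions plus discharges on the
#' same percentage scale) and the mean clinical complexity level of in-house
#' patients. A hospital's denominator is its busiest day of the year --
#' the peak census by default, or the peak admission count with
#' `peak = "admissions"`.
#'
#' @param records Filtered episode table.
#' @param year_length Days in the study year.
#' @param weekday_of_day1 Weekday of day 1 (1 = Monday .. 7 = Sunday).
#' @param peak Peak-day convention for the percentage denominator.
#' @return A `data.table` with one row per hospital-day: `hospital_id`, `day`,
#'   `census`, `admissions`, `discharges`, `cu`, `turnover`, `mean_pccl`
#'   (`NA` when the ward is empty), `is_weekend`.
#' @export
build_daily_series <- function(records, year_length = 365L,
                               weekday_of_day1 = 7L,
                               peak = c("census", "admissions")) {
  peak <- match.arg(peak)
  rec <- validate_records(records)
  hospitals <- sort(unique(rec$hospital_id))
  grid <- CJ(hospital_id = hospitals, day = seq_len(as.integer(year_length)))
  # presence expanded over in-year days; cheap at cohort scale
  pres <- rec[, {
    first <- pmax(admission_day, 1L)
    last <- pmin(last_present, as.integer(year_length))
    keep <- first <= last
    n <- last[keep] - first[keep] + 1L
    .(day = sequence(n) + rep(first[keep], n) - 1L,
      pccl = rep(pccl[keep], n))
  }, by = hospital_id]
  cens <- pres[, .(census = .N, mean_pccl = mean(pccl)),
               by = .(hospital_id, day)]
  adm <- rec[admission_day >= 1L & admission_day <= year_length,
             .(admissions = .N), by = .(hospital_id, day = admission_day)]
  dis <- rec[discharge_day >= 1L & discharge_day <= year_length,
             .(discharges = .N), by = .(hospital_id, day = discharge_day)]
  hd <- cens[grid, on = c("hospital_id", "day")]
  hd <- adm[hd, on = c("hospital_id", "day")]
  hd <- dis[hd, on = c("hospital_id", "day")]
  for (col in c("census", "admissions", "discharges"))
    hd[is.na(get(col)), (col) := 0L]
  peak_col <- if (peak == "census") "census" else "admissions"
  hd[, peak := max(get(peak_col)), by = hospital_id]
  hd[, cu := fifelse(peak > 0L, 100 * census / peak, 0)]
  hd[, turnover := fifelse(peak > 0L, 100 * (admissions + discharges) / peak, 0)]
  hd[, peak := NULL]
  hd[, is_weekend := is_weekend_day(day, weekday_of_day1)]
  setcolorder(hd, c("hospital_id", "day", "census", "admissions", "discharges",
                    "cu", "turnover", "mean_pccl", "is_weekend"))
  setorder(hd, hospital_id, day)
  hd[]
}

#' Hospital-specific exposure thresholds
#'
#' For each hospital, the threshold is the `p`-th linear-interpolation sample
#' quantile of its daily capacity-utilization series; a day is classified as
#' high exposure when its capacity utilization is greater than or equal to the
#' threshold (ties count as exposed).
#'
#' @param hospital_days Daily series from [build_daily_series()], or any
#'   data.frame with `hospital_id` and `cu` columns.
#' @param p Percentile in (0, 100].
#' @return A `data.table` with `hospital_id`, `percentile`, `threshold`.
#' @export
#' @examples
#' hd <- data.frame(hospital_id = 1L, cu = 1:20)
#' derive_threshold(hd, 85)  # threshold 17.15
derive_threshold <- function(hospital_days, p = 85) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 100)
    config_error("percentile must be a single value in (0, 100]")
  hd <- as.data.table(hospital_days)
  empty <- hd[, .(n = sum(!is.na(cu))), by = hospital_id][n == 0L]
  if (nrow(empty))
    validation_error(paste("empty capacity-utilization series for hospital",
                           empty$hospital_id[1]))
  out <- hd[, .(percentile = p, threshold = quantile7(cu, p)),
            by = hospital_id]
  setorder(out, hospital_id)
  out[]
}

#' Flag high-exposure hospital-days
#'
#' @param hospital_days Daily series from [build_daily_series()].
#' @param thresholds Threshold table from [derive_threshold()].
#' @return The daily series with an added logical `exposed` column
#'   (`cu >= threshold`, ties exposed).
#' @export
flag_exposure <- function(hospital_days, thresholds) {
  hd <- copy(as.data.table(hospital_days))
  thr <- as.data.table(thresholds)[, .(hospital_id, threshold)]
  hd <- thr[hd, on = "hospital_id"]
  if (anyNA(hd$threshold))
    validation_error("missing threshold for some hospital in the daily series")
  hd[, exposed := cu >= threshold]
  hd[]
}

#' Expand episodes into the censored 14-day person-day table
#'
#' Builds one row per at-risk stay-day: day index `t` starting at 1 on the
#' admission day, stopping at discharge, death or day `max_days`, whichever
#' comes first. Each row carries the binary exposure `A` of the patient's
#' hospital on that calendar day, the cumulative exposed-day count `cumA`
#' (including day `t` by default; with `exposure_lag = TRUE` only days before
#' `t` count), lagged exposure history (`A_lag`, `cumA_lag`), the
#' hospital-day time-varying confounders (`turnover`, `mean_pccl`), the
#' hospital's continuous utilization on the same and previous calendar day
#' (`cu`, `cu_lag`), baseline covariates, and the death indicator `Y`
#' (1 only on the death day).
#'
#' @param records Filtered episode table.
#' @param hospital_days Daily series from [build_daily_series()].
#' @param thresholds Threshold table from [derive_threshold()].
#' @param max_days Follow-up cap in days.
#' @param exposure_lag If `TRUE`, `cumA` excludes the current day's exposure.
#' @return A `data.table`, one row per person-day.
#' @export
expand_person_days <- function(records, hospital_days, thresholds,
                               max_days = 14L, exposure_lag = FALSE) {
  rec <- validate_records(records)
  hd <- flag_exposure(hospital_days, thresholds)
  setorder(hd, hospital_id, day)
  # previous calendar day's utilization of the patient's hospital (day 1 has
  # no predecessor and falls back to its own value)
  hd[, cu_lag := shift(cu), by = hospital_id]
  hd[is.na(cu_lag), cu_lag := cu]
  rec[, n_present := last_present - admission_day + 1L]
  pd <- rec[rep(seq_len(.N), pmin(n_present, as.integer(max_days)))]
  pd[, t := rowid(patient_id)]
  pd[, day := admission_day + t - 1L]
  pd <- hd[, .(hospital_id, day, A = as.integer(exposed), cu, cu_lag,
               turnover, mean_pccl)][
    pd, on = c("hospital_id", "day")]
  if (anyNA(pd$A))
    validation_error("person-day maps outside the available hospital-day series (were inclusion filters applied?)")
  setorder(pd, patient_id, t)
  pd[, cumA := cumsum(A), by = patient_id]
  pd[, A_lag := shift(A, fill = 0L), by = patient_id]
  pd[, cumA_lag := cumA - A]
  if (exposure_lag) pd[, cumA := cumA_lag]
  pd[, Y := as.integer(died & !is.na(death_day) & day == death_day)]
  pd[, age_num := as.numeric(age_group)]
  pd[, female := as.integer(sex == "female")]
  pd[, comorb_class := comorbidity_class(elixhauser_weight)]
  pd[, c("n_present", "last_present", "discharge_day", "death_day") := NULL]
  setcolorder(pd, c("patient_id", "hospital_id", "hospital_type", "t", "day",
                    "A", "cumA", "A_lag", "cumA_lag", "turnover", "mean_pccl",
                    "Y"))
  pd[]
}

#' Read patient episode records from CSV
#'
#' Reads the documented episode CSV contract
#' (`patient_id,hospital_id,hospital_type,admission_date,discharge_date,died,death_date,sex,age_group,pccl,elixhauser_weight`
#' with ISO-8601 dates) and converts dates to study-year day indices relative
#' to `year_start`. Columns already named `*_day` with integer day indices
#' are passed through unchanged.
#'
#' @param path CSV file path.
#' @param year_start `Date` (or ISO string) of study-year day 1; required when
#'   the file carries dates.
#' @param weekday_of_day1 Weekday of day 1, used to derive
#'   `weekend_admission` when absent (defaults to the weekday of
#'   `year_start` when given).
#' @return A validated episode `data.table`.
#' @export
read_patient_records <- function(path, year_start = NULL,
                                 weekday_of_day1 = NULL) {
  rec <- fread(path)
  date_cols <- c(admission_date = "admission_day",
                 discharge_date = "discharge_day", death_date = "death_day")
  if (any(names(date_cols) %in% names(rec))) {
    if (is.null(year_start))
      config_error("year_start is required to convert ISO dates to day indices")
    year_start <- as.Date(year_start)
    for (dc in names(date_cols)) {
      if (!dc %in% names(rec)) next
      d <- as.Date(as.character(rec[[dc]]), format = "%Y-%m-%d")
      bad <- which(!is.na(rec[[dc]]) & nzchar(as.character(rec[[dc]])) & is.na(d))
      if (length(bad))
        validation_error(sprintf("row %d: unparseable date in %s", bad[1], dc))
      rec[, (date_cols[[dc]]) := as.integer(d - year_start) + 1L]
      rec[, (dc) := NULL]
    }
    if (is.null(weekday_of_day1))
      weekday_of_day1 <- as.integer(format(year_start, "%u"))
  }
  if (!"death_day" %in% names(rec)) rec[, death_day := NA_integer_]
  if (!"died" %in% names(rec)) rec[, died := !is.na(death_day)]
  rec[, died := as.logical(died)]
  if (!"weekend_admission" %in% names(rec)) {
    if (is.null(weekday_of_day1))
      config_error("weekday_of_day1 (or year_start) needed to derive weekend_admission")
    rec[, weekend_admission := is_weekend_day(admission_day, weekday_of_day1)]
  }
  validate_records(rec)
}
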