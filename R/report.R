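# Descriptive reporting: Table-1-style cohort characteristics with 14-day
# death counts and rates, shared count-to-percent arithmetic, and per-hospital
# distribution summaries of the time-varying covariates.

#' Percentage from event and total counts
#'
#' Shared helper for every descriptive-table cell: `100 * events / total`,
#' rounded half away from zero to one decimal place (printed-table style).
#'
#' @param events,total Non-negative counts with `events <= total`,
#'   `total > 0`.
#' @return Percentage rounded to one decimal.
#' @export
#' @examples
#' rate_from_counts(16998, 1152506)  # 1.5
rate_from_counts <- function(events, total) {
  if (any(total <= 0)) validation_error("total must be positive")
  if (any(events < 0 | events > total))
    validation_error("events must lie in [0, total]")
  round_half_up(100 * events / total, 1)
}

tally_stratum <- function(rec, variable, level_vec, deaths14) {
  dt <- data.table(level = level_vec, d = deaths14)
  out <- dt[, .(n = .N, deaths = sum(d)), by = level]
  out[, variable := variable]
  out[, death_pct := rate_from_counts(deaths, n)]
  out[, level := as.character(level)]
  setcolorder(out, c("variable", "level", "n", "deaths", "death_pct"))
  out
}

#' Table-1-style descriptive statistics
#'
#' Counts and 14-day in-hospital death rates (deaths within 14 days of
#' admission) overall and by sex, age group (decade bins), hospital type,
#' comorbidity-weight class, clinical complexity level, admission weekday and
#' weekday/weekend admission.
#'
#' @param records Filtered episode table.
#' @param weekday_of_day1 Weekday of study-year day 1 (1 = Monday ..
#'   7 = Sunday), used to name admission weekdays.
#' @return A `data.table` of class `table_one` with columns `variable`,
#'   `level`, `n`, `deaths`, `death_pct`.
#' @export
table_one <- function(records, weekday_of_day1 = 7L) {
  rec <- validate_records(records)
  if (nrow(rec) == 0L) validation_error("empty cohort")
  deaths14 <- rec$died & !is.na(rec$death_day) &
    (rec$death_day - rec$admission_day + 1L) <= 14L
  wd <- factor(weekday_names[weekday_of_day(rec$admission_day, weekday_of_day1)],
               levels = weekday_names)
  out <- rbindlist(list(
    tally_stratum(rec, "Overall", rep("Total", nrow(rec)), deaths14),
    tally_stratum(rec, "Sex", factor(rec$sex, levels = c("male", "female")),
                  deaths14),
    tally_stratum(rec, "Age group", age_decade_label(rec$age_group), deaths14),
    tally_stratum(rec, "Hospital type",
                  factor(hospital_type_labels[rec$hospital_type],
                         levels = hospital_type_labels), deaths14),
    tally_stratum(rec, "Comorbidity class",
                  comorbidity_class(rec$elixhauser_weight), deaths14),
    tally_stratum(rec, "PCCL", factor(rec$pccl, levels = 0:4), deaths14),
    tally_stratum(rec, "Admission weekday", wd, deaths14),
    tally_stratum(rec, "Admission period",
                  factor(ifelse(rec$weekend_admission, "Weekends", "Weekdays"),
                         levels = c("Weekdays", "Weekends")), deaths14)
  ))
  setattr(out, "class", c("table_one", class(out)))
  out
}

#' Render a descriptive table as Markdown
#'
#' @param x A `table_one`.
#' @return Character vector of Markdown lines.
#' @export
format_table_one_markdown <- function(x) {
  c("| Variable | Level | N | 14-day deaths (%) |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %d | %d (%.1f) |",
            x$variable, x$level, x$n, x$deaths, x$death_pct))
}

#' Per-hospital distribution summaries of time-varying covariates
#'
#' Median, interquartile range and min-max of daily capacity utilization,
#' patient turnover and mean clinical complexity per hospital, with the
#' exposure threshold attached when supplied.
#'
#' @param hospital_days Daily series from [build_daily_series()].
#' @param thresholds Optional threshold table from [derive_threshold()].
#' @param hospital_types Optional named vector mapping hospital id to type.
#' @return A `data.table` with one row per hospital and covariate.
#' @export
covariate_distribution_summary <- function(hospital_days, thresholds = NULL,
                                           hospital_types = NULL) {
  hd <- as.data.table(hospital_days)
  if (nrow(hd) == 0L) validation_error("empty daily series")
  long <- melt(hd, id.vars = c("hospital_id", "day"),
               measure.vars = c("cu", "turnover", "mean_pccl"),
               variable.name = "variable", value.name = "value")
  out <- long[!is.na(value),
              .(median = median(value),
                q25 = quantile7(value, 25), q75 = quantile7(value, 75),
                min = min(value), max = max(value)),
              by = .(hospital_id, variable)]
  if (!is.null(thresholds)) {
    thr <- as.data.table(thresholds)[, .(hospital_id, threshold)]
    out <- thr[out, on = "hospital_id"]
    out[variable != "cu", threshold := NA_real_]
  }
  if (!is.null(hospital_types))
    out[, hospital_type := hospital_types[as.character(hospital_id)]]
  setorder(out, hospital_id, variable)
  out[]
}

#' Violin-style plot of daily capacity utilization per hospital
#'
#' @param hospital_days Daily series from [build_daily_series()].
#' @param thresholds Optional threshold table; thresholds are drawn as
#'   horizontal marks per hospital.
#' @return A ggplot object.
#' @export
plot_cu_distribution <- function(hospital_days, thresholds = NULL) {
  hd <- as.data.table(hospital_days)
  p <- ggplot2::ggplot(hd, ggplot2::aes(x = factor(hospital_id), y = cu)) +
    ggplot2::geom_violin(fill = "steelblue", alpha = 0.5) +
    ggplot2::labs(x = "hospital", y = "daily capacity utilization (%)",
                  title = "Annual distribution of daily capacity utilization") +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    thr <- as.data.table(thresholds)
    p <- p + ggplot2::geom_point(
      data = thr, ggplot2::aes(x = factor(hospital_id), y = threshold),
      shape = 95, size = 8, colour = "firebrick")
  }
  p
}
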