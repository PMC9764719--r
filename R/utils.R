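# Shared internal helpers: quantile convention, rounding, weekday arithmetic,
# and classed error conditions.

# Sample quantile with linear interpolation between order statistics
# (stats::quantile type 7); p on the 0-100 percentile scale.
quantile7 <- function(x, p) {
  stats::quantile(x, probs = p / 100, type = 7, names = FALSE, na.rm = FALSE)
}

# Round half away from zero (printed-table style), not banker's rounding.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Weekday of a study-year day index: 1 = Monday .. 7 = Sunday.
weekday_of_day <- function(day, weekday_of_day1) {
  ((as.integer(weekday_of_day1) - 1L + as.integer(day) - 1L) %% 7L) + 1L
}

is_weekend_day <- function(day, weekday_of_day1) {
  weekday_of_day(day, weekday_of_day1) >= 6L
}

weekday_names <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
                   "Saturday", "Sunday")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers/tests can distinguish failure modes.
occmsm_error <- function(msg, class) {
  stop(structure(
    class = c(class, "occmsm_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

config_error     <- function(msg) occmsm_error(msg, "occmsm_config_error")
validation_error <- function(msg) occmsm_error(msg, "occmsm_validation_error")
estimation_error <- function(msg) occmsm_error(msg, "occmsm_estimation_error")
precision_error  <- function(msg) occmsm_error(msg, "occmsm_precision_error")

# Comorbidity-burden classes used for adjustment (reference: negative weights).
comorb_levels <- c("<0", "0", ">0-<5", ">=5")

#' Classify a numeric comorbidity weight into analysis classes
#'
#' Bins a numeric comorbidity burden score (Elixhauser-type weighting) into the
#' four classes used for adjustment: negative, zero, positive below five, and
#' five or more. The negative class is the reference level.
#'
#' @param w Numeric vector of comorbidity weights.
#' @return A factor with levels `"<0"`, `"0"`, `">0-<5"`, `">=5"`.
#' @export
#' @examples
#' comorbidity_class(c(-2, 0, 3.5, 8))
comorbidity_class <- function(w) {
  if (!is.numeric(w)) validation_error("comorbidity weight must be numeric")
  cls <- ifelse(w < 0, "<0", ifelse(w == 0, "0", ifelse(w < 5, ">0-<5", ">=5")))
  factor(cls, levels = comorb_levels)
}

# 5-year age bands 1..19 (0-4 .. 90+), collapsed to the decade labels used in
# descriptive tables.
age_band_labels <- c(paste0(seq(0, 85, by = 5), "-", seq(4, 89, by = 5)), "90+")

age_decade_label <- function(band) {
  cuts <- c("0-19 years" = 4L, "20-29 years" = 6L, "30-39 years" = 8L,
            "40-49 years" = 10L, "50-59 years" = 12L, "60-69 years" = 14L,
            "70-79 years" = 16L, "80-89 years" = 18L, "90+ years" = 19L)
  lab <- names(cuts)[findInterval(band, c(0L, cuts[-length(cuts)]) + 1L)]
  factor(lab, levels = names(cuts))
}

hospital_type_labels <- c("University (level 1)", "Tertiary care (level 2)",
                          "Large basic (level 3)", "Medium basic (level 4)",
                          "Small basic (level 5)")
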