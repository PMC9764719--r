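# Stabilized inverse-probability-of-treatment weights for the time-varying
# binary high-occupancy exposure: pooled logistic numerator/denominator
# models, within-patient cumulative weight products, percentile truncation and
# diagnostics.

# Remove right-hand-side terms that are constant in `data` (a saturated or
# degenerate design would otherwise break the contrasts machinery).
drop_constant_terms <- function(formula, data) {
  rhs <- attr(stats::terms(formula), "term.labels")
  varying <- vapply(rhs, function(term) {
    v <- tryCatch(eval(parse(text = term), envir = data),
                  error = function(e) NULL)
    is.null(v) || length(unique(v)) > 1L
  }, TRUE)
  if (all(varying)) return(formula)
  lhs <- as.character(formula)[2]
  kept <- rhs[varying]
  as.formula(paste(lhs, "~", if (length(kept)) paste(kept, collapse = " + ")
                   else "1"),
             env = environment(formula))
}

#' Default exposure-model formulas
#'
#' The numerator model conditions the daily exposure probability on exposure
#' history (previous-day flag and lagged cumulative count), the stay-day
#' index and baseline covariates; the denominator adds the measured
#' time-varying hospital-day confounders: patient turnover and mean clinical
#' complexity, plus (optionally, `cu_lag = TRUE`) the previous calendar day's
#' continuous capacity utilization. The lagged-utilization term captures
#' occupancy persistence -- bed occupancy is an accumulating process, so the
#' previous day's level predicts today's exposure far better than the binary
#' flag alone -- at the price of sharper fitted probabilities and heavier
#' weight tails.
#'
#' @param cu_lag Include the lagged continuous utilization in the
#'   denominator?
#' @return A model formula.
#' @export
default_numerator_formula <- function() {
  A ~ A_lag + cumA_lag + factor(t) + age_num + female +
    factor(hospital_type) + comorb_class + weekend_admission
}

#' @rdname default_numerator_formula
#' @export
default_denominator_formula <- function(cu_lag = FALSE) {
  base <- A ~ A_lag + cumA_lag + factor(t) + age_num + female +
    factor(hospital_type) + comorb_class + weekend_admission +
    turnover + mean_pccl
  if (cu_lag) stats::update(base, . ~ . + cu_lag) else base
}

check_exposure_fit <- function(fit, label) {
  if (!fit$converged)
    estimation_error(paste(label, "exposure model did not converge"))
  cf <- coef(fit)
  cf <- cf[names(cf) != "(Intercept)"]
  huge <- which(!is.na(cf) & abs(cf) > 15)
  if (length(huge))
    estimation_error(sprintf(
      "%s exposure model shows separation on term '%s' (|coef| > 15)",
      label, names(cf)[huge[1]]))
  invisible(fit)
}

#' Fit numerator and denominator exposure models
#'
#' Fits two pooled logistic regressions for the daily probability of high
#' exposure across all person-days: the numerator model conditions on
#' exposure history (previous-day exposure and lagged cumulative exposure),
#' the day index and baseline covariates; the denominator model additionally
#' conditions on the time-varying hospital-day confounders (patient turnover
#' and mean clinical complexity). Their fitted probabilities form the
#' stabilized-weight ratio.
#'
#' @param persondays Person-day table from [expand_person_days()].
#' @param numerator,denominator Model formulas; `NULL` uses the defaults
#'   described above. Terms constant in the data are dropped automatically.
#' @return An object of class `exposure_models`: list with elements
#'   `numerator`, `denominator` (glm fits) and `formulas`.
#' @export
fit_exposure_models <- function(persondays, numerator = NULL,
                                denominator = NULL) {
  pd <- as.data.table(persondays)
  if (length(unique(pd$A)) < 2L)
    estimation_error("exposure takes a single level; cannot fit exposure models")
  fn <- drop_constant_terms(numerator %||% default_numerator_formula(), pd)
  fd <- drop_constant_terms(denominator %||% default_denominator_formula(), pd)
  fit_num <- glm(fn, family = binomial(), data = pd)
  fit_den <- glm(fd, family = binomial(), data = pd)
  check_exposure_fit(fit_num, "numerator")
  check_exposure_fit(fit_den, "denominator")
  structure(list(numerator = fit_num, denominator = fit_den,
                 formulas = list(numerator = fn, denominator = fd)),
            class = "exposure_models")
}

#' @export
print.exposure_models <- function(x, ...) {
  cat("<exposure_models>\n  numerator:  ",
      deparse(x$formulas$numerator), "\n  denominator:",
      deparse(x$formulas$denominator), "\n")
  cat(sprintf("  log-likelihoods: num %.1f, den %.1f\n",
              as.numeric(stats::logLik(x$numerator)),
              as.numeric(stats::logLik(x$denominator))))
  invisible(x)
}

#' Stabilized weight from per-day probability ratios
#'
#' Low-level kernel of the weight computation: the day-`t` contribution is
#' the numerator probability of the observed exposure divided by the
#' denominator probability of the observed exposure (using one minus the
#' fitted probability on unexposed days), and the stabilized weight is the
#' cumulative product of contributions over the patient's stay-days in order.
#'
#' @param a Observed exposure (0/1) per person-day.
#' @param p_num,p_den Fitted probabilities of exposure (`a = 1`) from the
#'   numerator and denominator models.
#' @param id Patient identifier per row.
#' @param t Stay-day index per row.
#' @param eps Positivity guard; probabilities of the observed exposure
#'   outside `(eps, 1 - eps)` trigger a warning with the offending row count.
#' @return Numeric vector of stabilized weights, aligned with the input rows.
#' @export
#' @examples
#' stabilized_weight_product(a = c(1, 0), p_num = c(0.5, 0.5),
#'   p_den = c(0.8, 0.4), id = c(1, 1), t = c(1, 2))  # 0.625, 0.5208
stabilized_weight_product <- function(a, p_num, p_den, id, t, eps = 1e-9) {
  stopifnot(length(a) == length(p_num), length(a) == length(p_den),
            length(a) == length(id), length(a) == length(t))
  obs_num <- ifelse(a == 1, p_num, 1 - p_num)
  obs_den <- ifelse(a == 1, p_den, 1 - p_den)
  n_bad <- sum(obs_den < eps | obs_den > 1 - eps |
                 obs_num < eps | obs_num > 1 - eps)
  if (n_bad > 0)
    warning(sprintf(
      "possible positivity violation: %d person-day(s) with observed-exposure probability outside (%.0e, 1 - %.0e)",
      n_bad, eps, eps), call. = FALSE)
  dt <- data.table(row = seq_along(a), id = id, t = t,
                   contrib = obs_num / obs_den)
  setorder(dt, id, t)
  dt[, sw := cumprod(contrib), by = id]
  setorder(dt, row)
  dt$sw
}

#' Compute stabilized inverse-probability-of-treatment weights
#'
#' @param models Fitted [fit_exposure_models()] object.
#' @param persondays Person-day table the models were (or could have been)
#'   fitted on.
#' @return A `data.table` of class `weight_set` with one row per person-day:
#'   `patient_id`, `t`, `p_num`, `p_den` (fitted probabilities of exposure),
#'   and the stabilized weight `sw`.
#' @export
compute_stabilized_weights <- function(models, persondays) {
  if (!inherits(models, "exposure_models"))
    validation_error("models must come from fit_exposure_models()")
  pd <- as.data.table(persondays)
  p_num <- predict(models$numerator, newdata = pd, type = "response")
  p_den <- predict(models$denominator, newdata = pd, type = "response")
  ws <- data.table(patient_id = pd$patient_id, t = pd$t,
                   p_num = p_num, p_den = p_den,
                   sw = stabilized_weight_product(pd$A, p_num, p_den,
                                                  pd$patient_id, pd$t))
  setattr(ws, "class", c("weight_set", class(ws)))
  ws
}

#' Truncate stabilized weights at percentile bounds
#'
#' Weights below the lower percentile of the weight distribution are raised
#' to it and weights above the upper percentile lowered to it (winsorizing),
#' the usual guard against extreme weights from near-positivity violations.
#'
#' @param weights A `weight_set` from [compute_stabilized_weights()].
#' @param lower_pct,upper_pct Percentile bounds (defaults 1 and 99).
#' @return A new `weight_set` with truncated `sw`; attributes `bounds`
#'   (the two percentile values) and `n_modified`.
#' @export
truncate_weights <- function(weights, lower_pct = 1, upper_pct = 99) {
  if (!is.numeric(lower_pct) || !is.numeric(upper_pct) ||
      lower_pct >= upper_pct)
    config_error("lower_pct must be strictly below upper_pct")
  if (nrow(weights) == 0L) validation_error("empty weight set")
  ws <- copy(as.data.table(weights))
  lo <- quantile7(ws$sw, lower_pct)
  hi <- quantile7(ws$sw, upper_pct)
  n_mod <- sum(ws$sw < lo | ws$sw > hi)
  ws[, sw := pmin(pmax(sw, lo), hi)]
  setattr(ws, "class", c("weight_set", setdiff(class(ws), "weight_set")))
  setattr(ws, "bounds", c(lower = lo, upper = hi))
  setattr(ws, "n_modified", n_mod)
  ws
}

#' Summarize a weight distribution
#'
#' Returns the summaries used to judge weight behaviour -- mean, median,
#' interquartile range, minimum and maximum -- and flags a mean deviating
#' from one by more than 0.05 as a likely sign of exposure-model
#' misspecification.
#'
#' @param weights A `weight_set` or numeric vector of weights.
#' @return A list of class `weight_diagnostics`: `mean`, `median`, `q25`,
#'   `q75`, `min`, `max`, `n`, `misspecification_flag`.
#' @export
weight_diagnostics <- function(weights) {
  sw <- if (is.numeric(weights)) weights else as.data.table(weights)$sw
  if (length(sw) == 0L) validation_error("empty weight set")
  out <- list(mean = mean(sw), median = median(sw),
              q25 = quantile7(sw, 25), q75 = quantile7(sw, 75),
              min = min(sw), max = max(sw), n = length(sw),
              misspecification_flag = abs(mean(sw) - 1) > 0.05)
  class(out) <- "weight_diagnostics"
  out
}

#' @export
print.weight_diagnostics <- function(x, ...) {
  cat(sprintf(
    "stabilized weights (n = %d): mean %.3f, median (IQR) %.2f (%.2f to %.2f), min-max %.2f-%.2f\n",
    x$n, x$mean, x$median, x$q25, x$q75, x$min, x$max))
  if (x$misspecification_flag)
    cat("  warning: mean deviates from 1 by > 0.05 -- possible exposure-model misspecification\n")
  invisible(x)
}

#' Density plot of stabilized weights
#'
#' @param weights A `weight_set` or numeric vector.
#' @return A ggplot object.
#' @export
plot_weight_density <- function(weights) {
  sw <- if (is.numeric(weights)) weights else as.data.table(weights)$sw
  ggplot2::ggplot(data.frame(sw = sw), ggplot2::aes(x = sw)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "stabilized weight", y = "density",
                  title = "Stabilized IPTW distribution") +
    ggplot2::theme_minimal()
}
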