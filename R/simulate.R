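# Synthetic multi-hospital cohort generator with a known causal structure:
# Poisson admissions with weekday/weekend modulation, geometric-type length of
# stay, occupancy feedback on next-day admission/discharge intensity, an
# unmeasured AR(1) staffing process driving both turnover and the daily death
# hazard, and a logistic death hazard with a configurable effect of cumulative
# high-occupancy exposure. A randomized-exposure oracle computes the marginal
# causal estimand targeted by the analysis models.

#' Default baseline covariate mix
#'
#' Sampling probabilities for the simulated patient mix: sex, 5-year age band
#' (1-19, i.e. 0-4 years up to 90+), clinical complexity level (PCCL 0-4) and
#' comorbidity-weight class. The defaults reproduce the marginal composition
#' of a large general-hospital inpatient population (53.4% female, ~61% with
#' no clinical complexity, ~30% with comorbidity weight of five or more).
#'
#' @return A list with elements `p_female`, `age_probs` (length 19),
#'   `pccl_probs` (length 5), `comorb_probs` (length 4, classes
#'   `<0`, `0`, `>0-<5`, `>=5`).
#' @export
default_covariate_mix <- function() {
  total <- 1152506
  decades <- c(152887, 85498, 125141, 99401, 139695, 163193, 192614, 156026,
               38051) / total
  # split each decade evenly over its 5-year bands (0-19 covers four bands)
  age_probs <- c(rep(decades[1] / 4, 4),
                 rep(decades[2:8] / 2, each = 2),
                 decades[9])
  comorb <- c(197262, 532629, 76495, 345501)
  list(
    p_female = 615743 / total,
    age_probs = age_probs / sum(age_probs),
    pccl_probs = c(705437, 16933, 130866, 174576, 124694) / total,
    comorb_probs = comorb / sum(comorb)
  )
}

#' Default conditional covariate effects on the daily death hazard
#'
#' Log-odds effects entering the simulated daily death hazard: sex, age band
#' (per 5-year step), clinical complexity (per PCCL level), comorbidity class
#' (versus the negative-weight reference), weekend admission, and hospital
#' type (versus university hospitals).
#'
#' @return Named list of log-odds effects.
#' @export
default_beta_covariates <- function() {
  list(
    female = -0.27,
    age_band = 0.16,
    pccl = 0.45,
    comorb = c("<0" = 0, "0" = 1.09, ">0-<5" = 0.85, ">=5" = 2.06),
    weekend = 0.09,
    hospital_type = c(0, 0.009, -0.141, -0.118, 0.523)
  )
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic-cohort
#' generator. Defaults describe a mid-sized five-hospital system observed for
#' one year: expected peak censuses spanning university-sized to small basic
#' hospitals, admission rates implied by a 6.2-day mean length of stay,
#' weekend admissions at roughly half the weekday rate, an AR(1) unmeasured
#' staffing process that speeds discharges when staffing is good and lowers
#' the death hazard, and next-day feedback of high occupancy onto both
#' admission and discharge intensity.
#'
#' @param n_hospitals Number of hospitals.
#' @param hospital_sizes Expected peak census per hospital (capacity proxy);
#'   admission rates default to `hospital_sizes / los_mean`.
#' @param hospital_types Hospital type 1-5 per hospital.
#' @param year_length Days in the study year (>= 28).
#' @param weekday_of_day1 Weekday of day 1 (1 = Monday .. 7 = Sunday).
#' @param admission_rate_base Expected admissions/day per hospital on
#'   weekdays; `NULL` derives it from `hospital_sizes`.
#' @param weekend_admission_factor Multiplier in (0, 1] on weekend admission
#'   rates.
#' @param los_mean Mean length of stay in days (geometric-type stay lengths).
#' @param covariate_mix See [default_covariate_mix()].
#' @param feedback_strength Occupancy feedback `delta`: a high-utilization day
#'   multiplies the next day's admission rate by `exp(-delta)` and adds
#'   `delta` to the log-odds of discharge.
#' @param staffing_ar_coef,staffing_sd AR(1) coefficient and innovation SD of
#'   the unmeasured per-hospital staffing process `U`.
#' @param staffing_turnover_effect Log-odds effect of `U` on daily discharge
#'   probability (staffing drives patient turnover).
#' @param severity_ar_coef,severity_sd AR(1) coefficient and innovation SD of
#'   the per-hospital admission-severity wave `S` (observable through the
#'   daily mean clinical complexity of in-house patients).
#' @param severity_amplitude Log-odds tilt of the admitted casemix per unit
#'   of `S` and PCCL level: on high-severity days the admitted patients skew
#'   towards higher clinical complexity.
#' @param los_pccl_effect Reduction of the daily discharge log-odds per PCCL
#'   level above the population mean: clinically complex patients stay
#'   longer, so severity waves accumulate into bed occupancy.
#' @param mortality_intercept Baseline daily death-hazard log-odds `alpha0`.
#' @param beta_cum_exposure Per-day log-odds effect of cumulative
#'   high-occupancy exposure on the daily death hazard (the causal parameter).
#' @param beta_covariates See [default_beta_covariates()].
#' @param gamma_staffing Log-odds effect of `U` on the daily death hazard
#'   (negative: better staffing, fewer deaths).
#' @param exposure_percentile Percentile defining the high-occupancy
#'   threshold.
#' @param exposure_lag If `TRUE` the hazard uses cumulative exposure through
#'   the previous day; default counts the current day.
#' @param seed Master seed; all random streams derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_hospitals = 5L,
                       hospital_sizes = c(175, 135, 90, 65, 40),
                       hospital_types = seq_len(n_hospitals),
                       year_length = 365L,
                       weekday_of_day1 = 7L,
                       admission_rate_base = NULL,
                       weekend_admission_factor = 0.48,
                       los_mean = 6.2,
                       covariate_mix = default_covariate_mix(),
                       feedback_strength = 0.3,
                       staffing_ar_coef = 0.8,
                       staffing_sd = 0.4,
                       staffing_turnover_effect = 0.25,
                       severity_ar_coef = 0.9,
                       severity_sd = 0.25,
                       severity_amplitude = 0.3,
                       los_pccl_effect = 0.12,
                       mortality_intercept = -10.2,
                       beta_cum_exposure = log(1.02),
                       beta_covariates = default_beta_covariates(),
                       gamma_staffing = -0.4,
                       exposure_percentile = 85,
                       exposure_lag = FALSE,
                       seed = 1L) {
  cfg <- list(n_hospitals = as.integer(n_hospitals),
              hospital_sizes = hospital_sizes,
              hospital_types = as.integer(hospital_types),
              year_length = as.integer(year_length),
              weekday_of_day1 = as.integer(weekday_of_day1),
              admission_rate_base = admission_rate_base %||%
                (hospital_sizes / los_mean),
              weekend_admission_factor = weekend_admission_factor,
              los_mean = los_mean,
              covariate_mix = covariate_mix,
              feedback_strength = feedback_strength,
              staffing_ar_coef = staffing_ar_coef,
              staffing_sd = staffing_sd,
              staffing_turnover_effect = staffing_turnover_effect,
              severity_ar_coef = severity_ar_coef,
              severity_sd = severity_sd,
              severity_amplitude = severity_amplitude,
              los_pccl_effect = los_pccl_effect,
              mortality_intercept = mortality_intercept,
              beta_cum_exposure = beta_cum_exposure,
              beta_covariates = beta_covariates,
              gamma_staffing = gamma_staffing,
              exposure_percentile = exposure_percentile,
              exposure_lag = isTRUE(exposure_lag),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(cond, msg) if (!isTRUE(cond)) config_error(msg)
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  chk(cfg$n_hospitals >= 1L, "n_hospitals must be >= 1")
  chk(num_ok(cfg$hospital_sizes) && length(cfg$hospital_sizes) == cfg$n_hospitals &&
        all(cfg$hospital_sizes > 0), "hospital_sizes must be positive, one per hospital")
  chk(length(cfg$hospital_types) == cfg$n_hospitals &&
        all(cfg$hospital_types %in% 1:5), "hospital_types must be 1-5, one per hospital")
  chk(cfg$year_length >= 28L, "year_length must be >= 28 days")
  chk(cfg$weekday_of_day1 %in% 1:7, "weekday_of_day1 must be 1-7")
  chk(num_ok(cfg$admission_rate_base) && all(cfg$admission_rate_base > 0) &&
        length(cfg$admission_rate_base) == cfg$n_hospitals,
      "admission_rate_base must be positive, one per hospital")
  chk(num_ok(cfg$weekend_admission_factor) &&
        cfg$weekend_admission_factor > 0 && cfg$weekend_admission_factor <= 1,
      "weekend_admission_factor must be in (0, 1]")
  chk(num_ok(cfg$los_mean) && cfg$los_mean > 0, "los_mean must be > 0")
  mix <- cfg$covariate_mix
  prob_ok <- function(p) num_ok(p) && all(p >= 0 & p <= 1) &&
    abs(sum(p) - 1) < 1e-8
  chk(num_ok(mix$p_female) && mix$p_female >= 0 && mix$p_female <= 1,
      "p_female must be a probability")
  chk(prob_ok(mix$age_probs) && length(mix$age_probs) == 19L,
      "age_probs must be 19 probabilities summing to 1")
  chk(prob_ok(mix$pccl_probs) && length(mix$pccl_probs) == 5L,
      "pccl_probs must be 5 probabilities summing to 1")
  chk(prob_ok(mix$comorb_probs) && length(mix$comorb_probs) == 4L,
      "comorb_probs must be 4 probabilities summing to 1")
  chk(num_ok(cfg$feedback_strength), "feedback_strength must be finite")
  chk(num_ok(cfg$staffing_ar_coef) && abs(cfg$staffing_ar_coef) < 1,
      "staffing_ar_coef must lie in (-1, 1)")
  chk(num_ok(cfg$staffing_sd) && cfg$staffing_sd >= 0,
      "staffing_sd must be >= 0")
  chk(num_ok(cfg$staffing_turnover_effect), "staffing_turnover_effect must be finite")
  chk(num_ok(cfg$severity_ar_coef) && abs(cfg$severity_ar_coef) < 1,
      "severity_ar_coef must lie in (-1, 1)")
  chk(num_ok(cfg$severity_sd) && cfg$severity_sd >= 0,
      "severity_sd must be >= 0")
  chk(num_ok(cfg$severity_amplitude), "severity_amplitude must be finite")
  chk(num_ok(cfg$los_pccl_effect), "los_pccl_effect must be finite")
  chk(num_ok(cfg$mortality_intercept), "mortality_intercept must be finite")
  chk(num_ok(cfg$beta_cum_exposure), "beta_cum_exposure must be finite")
  chk(num_ok(cfg$gamma_staffing), "gamma_staffing must be finite")
  chk(num_ok(cfg$exposure_percentile) && cfg$exposure_percentile > 0 &&
        cfg$exposure_percentile <= 100, "exposure_percentile must be in (0, 100]")
  b <- cfg$beta_covariates
  chk(all(vapply(b[c("female", "age_band", "pccl", "weekend")], num_ok, TRUE)) &&
        num_ok(b$comorb) && length(b$comorb) == 4L &&
        num_ok(b$hospital_type) && length(b$hospital_type) == 5L,
      "beta_covariates must provide female, age_band, pccl, weekend, comorb (4), hospital_type (5)")
  invisible(cfg)
}

ar1_series <- function(n, ar, sd) {
  x <- numeric(n)
  x[1] <- rnorm(1, 0, if (sd > 0) sd / sqrt(1 - ar^2) else 0)
  for (d in seq_len(n - 1L)) x[d + 1L] <- ar * x[d] + rnorm(1, 0, sd)
  x
}

# Bed dynamics for one hospital: Poisson admissions (weekday-modulated, damped
# the day after a high-occupancy day), a per-hospital AR(1) admission-severity
# wave tilting each day's admitted casemix (PCCL), per-patient end-of-day
# discharge draws (slowed for clinically complex patients, sped up by good
# staffing U and by yesterday's high occupancy), and the latent AR(1) staffing
# series. The within-year feedback flag compares the census with a running
# 85th-type percentile of the censuses seen so far.
simulate_hospital_dynamics <- function(cfg, h) {
  yl <- cfg$year_length
  delta <- cfg$feedback_strength
  kappa <- cfg$staffing_turnover_effect
  rate <- cfg$admission_rate_base[h]
  p0_logit <- qlogis(1 / cfg$los_mean)
  U <- ar1_series(yl, cfg$staffing_ar_coef, cfg$staffing_sd)
  S <- ar1_series(yl, cfg$severity_ar_coef, cfg$severity_sd)
  pccl_base <- cfg$covariate_mix$pccl_probs
  pccl_center <- sum((0:4) * pccl_base)
  adm_day <- integer(0)
  dis_day <- integer(0)
  pccl <- integer(0)
  active <- integer(0)
  census <- admN <- disN <- integer(yl)
  flag <- logical(yl)
  for (d in seq_len(yl)) {
    fb <- if (d > 1L) flag[d - 1L] else FALSE
    wk <- if (is_weekend_day(d, cfg$weekday_of_day1))
      cfg$weekend_admission_factor else 1
    n_new <- rpois(1L, rate * wk * exp(-delta * fb))
    if (n_new > 0L) {
      ids <- length(adm_day) + seq_len(n_new)
      adm_day <- c(adm_day, rep(d, n_new))
      dis_day <- c(dis_day, rep(NA_integer_, n_new))
      tilt <- pccl_base * exp(cfg$severity_amplitude * S[d] * (0:4))
      pccl <- c(pccl, sample.int(5L, n_new, replace = TRUE,
                                 prob = tilt / sum(tilt)) - 1L)
      active <- c(active, ids)
    }
    # the day's occupancy is measured after admissions arrive; discharges
    # resolve at the end of the day (the discharge day is the first free day)
    census[d] <- length(active)
    admN[d] <- n_new
    flag[d] <- census[d] > 0L && census[d] >= quantile7(census[seq_len(d)],
                                                        cfg$exposure_percentile)
    if (length(active)) {
      p_dis <- plogis(p0_logit + delta * fb + kappa * U[d] -
                        cfg$los_pccl_effect * (pccl[active] - pccl_center))
      out <- runif(length(active)) < p_dis
      dis_day[active[out]] <- d + 1L  # present through day d
      disN[d] <- sum(out)
      active <- active[!out]
    }
  }
  if (length(active)) {
    # stays running past the year end resolve at the baseline discharge rate
    extra <- rgeom(length(active),
                   plogis(p0_logit - cfg$los_pccl_effect *
                            (pccl[active] - pccl_center)))
    dis_day[active] <- yl + 1L + extra
  }
  list(adm_day = adm_day, dis_day = dis_day, pccl = pccl, census = census,
       admissions = admN, discharges = disN, U = U, S = S,
       flag_running = flag)
}

draw_covariates <- function(n, cfg) {
  mix <- cfg$covariate_mix
  comorb_cls <- sample.int(4L, n, replace = TRUE, prob = mix$comorb_probs)
  # numeric weight consistent with the sampled class
  ew <- numeric(n)
  ew[comorb_cls == 1L] <- -runif(sum(comorb_cls == 1L), 0.1, 4)
  ew[comorb_cls == 2L] <- 0
  ew[comorb_cls == 3L] <- runif(sum(comorb_cls == 3L), 0.1, 4.9)
  ew[comorb_cls == 4L] <- 5 + rexp(sum(comorb_cls == 4L), rate = 1)
  data.table(
    sex = ifelse(runif(n) < mix$p_female, "female", "male"),
    age_group = sample.int(19L, n, replace = TRUE, prob = mix$age_probs),
    elixhauser_weight = ew
  )
}

# Patient-level linear predictor of the daily death hazard (excluding the
# exposure and staffing terms).
baseline_linear_predictor <- function(rec, cfg) {
  b <- cfg$beta_covariates
  cfg$mortality_intercept +
    b$female * (rec$sex == "female") +
    b$age_band * rec$age_group +
    b$pccl * rec$pccl +
    unname(b$comorb[as.integer(comorbidity_class(rec$elixhauser_weight))]) +
    b$weekend * rec$weekend_admission +
    b$hospital_type[rec$hospital_type]
}

# Simulate daily deaths for in-house days within the year given per-hospital
# exposure flags; returns death stay-day per patient (NA if survives).
simulate_deaths <- function(rec, flags, U, cfg) {
  yl <- cfg$year_length
  last_in_year <- pmin(rec$dis_day - 1L, yl)
  n_days <- pmax(last_in_year - rec$adm_day + 1L, 0L)
  idx <- which(n_days > 0L)
  if (!length(idx)) return(rep(NA_integer_, nrow(rec)))
  pd <- data.table(
    row = rep(idx, n_days[idx]),
    stay_day = sequence(n_days[idx])
  )
  pd[, day := rec$adm_day[row] + stay_day - 1L]
  pd[, hospital_id := rec$hospital_id[row]]
  pd[, A := as.integer(flags[cbind(hospital_id, day)])]
  pd[, cumA := cumsum(A), by = row]
  if (cfg$exposure_lag) pd[, cumA := cumA - A]
  lp0 <- baseline_linear_predictor(rec, cfg)
  pd[, lp := lp0[row] + cfg$beta_cum_exposure * cumA +
       cfg$gamma_staffing * U[cbind(hospital_id, day)]]
  pd[, hit := runif(.N) < plogis(lp)]
  out <- rep(NA_integer_, nrow(rec))
  if (any(pd$hit)) {
    death <- pd[hit == TRUE, .(t_death = min(stay_day)), by = row]
    out[death$row] <- as.integer(death$t_death)
  }
  out
}

#' Generate a synthetic multi-hospital cohort with known causal truth
#'
#' Simulates one study year of inpatient episodes across hospitals. Bed
#' dynamics are simulated first (admissions, discharges, census, the latent
#' staffing process, and occupancy feedback); annual capacity-utilization
#' series and hospital-specific percentile thresholds then define the
#' high-occupancy exposure flags exactly as the analysis does; finally daily
#' deaths are drawn from a logistic hazard driven by cumulative exposure,
#' baseline covariates and the staffing process. Death takes precedence over
#' discharge on the same day, and a death truncates the stay.
#'
#' @param config A [sim_config()].
#' @return A list with `records` (episode `data.table` following the
#'   [validate_records()] contract) and `truth`, a list carrying the latent
#'   staffing series (`U`, hospitals x days), the generator's exposure flags
#'   and thresholds, the observed exposure prevalence, the causal parameter
#'   used, and the config. `truth$oracle_marginal_log_or` is `NA` until
#'   filled by [true_marginal_effect_oracle()].
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_hospitals = 2,
#'   hospital_sizes = c(40, 30), hospital_types = c(2, 5),
#'   year_length = 120, seed = 42))
#' nrow(cohort$records)
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)
  yl <- config$year_length
  dyn <- lapply(seq_len(config$n_hospitals), simulate_hospital_dynamics,
                cfg = config)
  census <- do.call(rbind, lapply(dyn, `[[`, "census"))
  U <- do.call(rbind, lapply(dyn, `[[`, "U"))
  cu <- 100 * census / pmax(apply(census, 1L, max), 1L)
  thresholds <- apply(cu, 1L, quantile7, p = config$exposure_percentile)
  flags <- cu >= thresholds
  recs <- rbindlist(lapply(seq_len(config$n_hospitals), function(h) {
    data.table(hospital_id = h,
               hospital_type = config$hospital_types[h],
               adm_day = dyn[[h]]$adm_day,
               dis_day = dyn[[h]]$dis_day,
               pccl = dyn[[h]]$pccl)
  }))
  recs <- cbind(recs, draw_covariates(nrow(recs), config))
  recs[, weekend_admission := is_weekend_day(adm_day, config$weekday_of_day1)]
  t_death <- simulate_deaths(recs, flags, U, config)
  recs[, died := !is.na(t_death)]
  recs[, death_day := fifelse(died, adm_day + t_death - 1L, NA_integer_)]
  recs[, dis_day := fifelse(died, death_day + 1L, dis_day)]
  setnames(recs, c("adm_day", "dis_day"), c("admission_day", "discharge_day"))
  recs[, patient_id := seq_len(.N)]
  setcolorder(recs, record_columns)
  truth <- list(
    U = U,
    S = do.call(rbind, lapply(dyn, `[[`, "S")),
    census = census,
    cu = cu,
    thresholds = thresholds,
    exposure_flags = flags,
    exposure_prevalence = mean(flags),
    beta_cum_exposure = config$beta_cum_exposure,
    oracle_marginal_log_or = NA_real_,
    config = config
  )
  list(records = validate_records(recs), truth = truth)
}

# Person-day table straight from generator internals under given exposure
# flags (used by the oracle; bypasses the threshold re-derivation that the
# observational analysis performs).
oracle_person_days <- function(rec, flags, t_death, cfg, max_days = 14L) {
  yl <- cfg$year_length
  last <- pmin(ifelse(is.na(t_death), rec$dis_day - 1L,
                      rec$adm_day + t_death - 1L), yl)
  keep <- rec$adm_day >= 1L & rec$adm_day <= yl - 14L
  n_days <- pmin(pmax(last - rec$adm_day + 1L, 0L), max_days)
  idx <- which(keep & n_days > 0L)
  pd <- data.table(row = rep(idx, n_days[idx]), t = sequence(n_days[idx]))
  pd[, day := rec$adm_day[row] + t - 1L]
  pd[, hospital_id := rec$hospital_id[row]]
  pd[, A := as.integer(flags[cbind(hospital_id, day)])]
  pd[, cumA := cumsum(A), by = row]
  if (cfg$exposure_lag) pd[, cumA := cumA - A]
  pd[, Y := as.integer(!is.na(t_death[row]) & t == t_death[row])]
  pd[, hospital_type := rec$hospital_type[row]]
  pd[, age_num := as.numeric(rec$age_group[row])]
  pd[, female := as.integer(rec$sex[row] == "female")]
  pd[, comorb_class := comorbidity_class(rec$elixhauser_weight[row])]
  pd[, pccl := rec$pccl[row]]
  pd[, weekend_admission := rec$weekend_admission[row]]
  pd[]
}

#' Randomized-exposure oracle for the marginal causal effect
#'
#' Computes the causal estimand targeted by the marginal structural model by
#' direct simulation: bed dynamics and covariates are generated exactly as in
#' [generate_cohort()], but the daily high-occupancy exposure is assigned
#' exogenously -- independent hospital-day Bernoulli draws at the
#' observational marginal prevalence, severing every pathway from confounders
#' or staffing into the exposure. Daily deaths are then drawn from the same
#' hazard using the randomized cumulative exposure, and an unweighted pooled
#' logistic regression of daily death on cumulative exposure plus baseline
#' covariates over the replicated cohorts returns the marginal per-day
#' log-odds effect.
#'
#' @param config A [sim_config()].
#' @param n_rep Number of replicate cohorts pooled into the fit.
#' @param seed Seed for the oracle's own random streams.
#' @param se_tol Optional precision requirement: error (class
#'   `occmsm_precision_error`) if the Monte-Carlo standard error exceeds it.
#' @return A list: `log_or` (oracle marginal per-day log-odds ratio), `mc_se`
#'   (cluster-robust Monte-Carlo standard error), `or`, `n_rep`,
#'   `n_persondays`, `exposure_prevalence`.
#' @export
true_marginal_effect_oracle <- function(config, n_rep = 20L, seed = 1L,
                                        se_tol = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  if (n_rep < 1L) config_error("n_rep must be >= 1")
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  yl <- config$year_length
  pieces <- vector("list", n_rep)
  prevs <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(subseeds[r])
    dyn <- lapply(seq_len(config$n_hospitals), simulate_hospital_dynamics,
                  cfg = config)
    census <- do.call(rbind, lapply(dyn, `[[`, "census"))
    U <- do.call(rbind, lapply(dyn, `[[`, "U"))
    cu <- 100 * census / pmax(apply(census, 1L, max), 1L)
    thresholds <- apply(cu, 1L, quantile7, p = config$exposure_percentile)
    prevalence <- mean(cu >= thresholds)
    prevs[r] <- prevalence
    flags_rand <- matrix(runif(length(cu)) < prevalence, nrow = nrow(cu))
    rec <- rbindlist(lapply(seq_len(config$n_hospitals), function(h)
      data.table(hospital_id = h, hospital_type = config$hospital_types[h],
                 adm_day = dyn[[h]]$adm_day, dis_day = dyn[[h]]$dis_day,
                 pccl = dyn[[h]]$pccl)))
    rec <- cbind(rec, draw_covariates(nrow(rec), config))
    rec[, weekend_admission := is_weekend_day(adm_day, config$weekday_of_day1)]
    t_death <- simulate_deaths(rec, flags_rand, U, config)
    pd <- oracle_person_days(rec, flags_rand, t_death, config)
    pd[, rep_id := r]
    pieces[[r]] <- pd
  }
  pd <- rbindlist(pieces)
  # the day-index term keeps the at-risk composition (long-stayers are
  # sicker) out of the cumulative-exposure coefficient
  fml <- Y ~ cumA + weekend_admission + factor(hospital_type) + comorb_class +
    age_num + female + factor(t)
  fml <- drop_constant_terms(fml, pd)
  fit <- glm(fml, family = binomial(), data = pd)
  if (!fit$converged)
    estimation_error("oracle pooled logistic did not converge")
  vc <- sandwich::vcovCL(fit, cluster = interaction(pd$rep_id, pd$hospital_id),
                         type = "HC0", cadjust = FALSE)
  est <- coef(fit)[["cumA"]]
  mc_se <- sqrt(vc["cumA", "cumA"])
  if (!is.null(se_tol) && mc_se > se_tol)
    precision_error(sprintf(
      "oracle Monte-Carlo SE %.4g exceeds requested precision %.4g; increase n_rep",
      mc_se, se_tol))
  list(log_or = est, mc_se = mc_se, or = exp(est), n_rep = n_rep,
       n_persondays = nrow(pd), exposure_prevalence = mean(prevs))
}
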