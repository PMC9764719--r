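# End-to-end orchestration: simulate or ingest episode records, derive the
# cohort tables, estimate weights, fit the MSM variants and write every
# artifact plus a manifest of key estimates.

#' Assemble and validate a pipeline configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"csv"` (read
#'   episode records from `input_csv`). Exactly one input mode.
#' @param sim List of [sim_config()] arguments (simulate mode).
#' @param input_csv Episode CSV path (csv mode).
#' @param year_start ISO date of study-year day 1 (csv mode with dates).
#' @param year_length,weekday_of_day1 Study-year layout.
#' @param percentile Exposure threshold percentile.
#' @param exposure `"cumulative"` or `"short"` primary exposure term.
#' @param truncation Percentile bounds `c(lower, upper)` for the
#'   truncated-weight variant, or `NULL` to skip it.
#' @param cluster Cluster level for robust variances.
#' @param sensitivity_percentiles Percentiles for the threshold sweep, or
#'   `NULL` to skip the sweep.
#' @param max_days Follow-up cap in days.
#' @param seed Master seed (overrides `sim$seed` in simulate mode).
#' @param output_dir Directory for artifacts, or `NULL` to skip writing.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "csv"), sim = list(),
                            input_csv = NULL, year_start = NULL,
                            year_length = 365L, weekday_of_day1 = 7L,
                            percentile = 85, exposure = "cumulative",
                            truncation = c(1, 99), cluster = "hospital",
                            sensitivity_percentiles = NULL, max_days = 14L,
                            seed = 1L, output_dir = NULL) {
  if (length(mode) != 1L || !mode %in% c("simulate", "csv"))
    config_error("exactly one input mode ('simulate' or 'csv') must be chosen")
  if (mode == "csv" && (is.null(input_csv) || !nzchar(input_csv)))
    config_error("csv mode requires input_csv")
  if (mode == "simulate" && !is.list(sim))
    config_error("sim must be a list of sim_config() arguments")
  if (!is.null(truncation) &&
      (length(truncation) != 2L || truncation[1] >= truncation[2]))
    config_error("truncation must be c(lower, upper) with lower < upper")
  structure(list(mode = mode, sim = sim, input_csv = input_csv,
                 year_start = year_start,
                 year_length = as.integer(year_length),
                 weekday_of_day1 = as.integer(weekday_of_day1),
                 percentile = percentile, exposure = exposure,
                 truncation = truncation, cluster = cluster,
                 sensitivity_percentiles = sensitivity_percentiles,
                 max_days = as.integer(max_days), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$truncation)) cfg$truncation <- as.numeric(cfg$truncation)
  do.call(pipeline_config, cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    occmsm_error(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 "occmsm_pipeline_error")
  })
}

msm_result_list <- function(fit) {
  c(list(terms = as.data.frame(fit)),
    attributes(fit)[c("n", "n_clusters", "n_events", "weighted")],
    list(weight_summary = attr(fit, "weight_summary")))
}

write_artifact <- function(obj, dir, name) {
  if (is.null(dir)) return(NULL)
  path <- file.path(dir, name)
  if (grepl("\\.csv$", name)) {
    fwrite(as.data.table(obj), path)
  } else if (grepl("\\.json$", name)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  } else {
    writeLines(obj, path)
  }
  path
}

#' Run the full analysis pipeline
#'
#' Sequences the whole study: obtain episode records (synthetic cohort or
#' CSV), apply inclusion filters, derive daily hospital series and
#' hospital-specific thresholds, expand person-days, fit exposure models and
#' stabilized weights, fit the weighted MSM with its unweighted comparator,
#' the short-term-exposure variant and (optionally) the truncated-weight
#' variant and the threshold sensitivity sweep, and produce descriptive
#' tables. All artifacts are written under `output_dir` when set, and a
#' manifest of artifact paths and key estimates is returned.
#'
#' @param config A `pipeline_config`, a list of [pipeline_config()]
#'   arguments, or a YAML path.
#' @param quiet Suppress progress messages?
#' @return The manifest: a list with artifact `paths`, key `estimates`
#'   (exposure log-odds and ORs per model variant), weight diagnostics,
#'   exclusion counts, the seed and package version.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(config$output_dir) &&
      !dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  paths <- list()

  truth <- NULL
  records <- stage("input", {
    if (config$mode == "simulate") {
      sim_args <- config$sim
      sim_args$seed <- config$seed
      if (is.null(sim_args$year_length)) sim_args$year_length <- config$year_length
      if (is.null(sim_args$weekday_of_day1))
        sim_args$weekday_of_day1 <- config$weekday_of_day1
      if (is.null(sim_args$exposure_percentile))
        sim_args$exposure_percentile <- config$percentile
      cohort <- generate_cohort(do.call(sim_config, sim_args))
      truth <<- cohort$truth
      cohort$records
    } else {
      read_patient_records(config$input_csv, config$year_start,
                           config$weekday_of_day1)
    }
  })
  say("input: %d episodes", nrow(records))
  paths$cohort <- write_artifact(records, config$output_dir, "cohort.csv")
  if (!is.null(truth))
    paths$sim_truth <- write_artifact(
      list(thresholds = truth$thresholds,
           exposure_prevalence = truth$exposure_prevalence,
           beta_cum_exposure = truth$beta_cum_exposure,
           seed = config$seed),
      config$output_dir, "sim_truth.json")

  filtered <- stage("inclusion_filters",
                    apply_inclusion_filters(records, config$year_length,
                                            quiet = quiet))
  hd <- stage("daily_series",
              build_daily_series(filtered, config$year_length,
                                 config$weekday_of_day1))
  thr <- stage("thresholds", derive_threshold(hd, config$percentile))
  pd <- stage("person_days",
              expand_person_days(filtered, hd, thr, config$max_days))
  say("person-days: %d rows, %d deaths", nrow(pd), sum(pd$Y))
  paths$hospital_days <- write_artifact(hd, config$output_dir, "hospital_days.csv")
  paths$thresholds <- write_artifact(thr, config$output_dir, "thresholds.csv")
  paths$person_days <- write_artifact(pd, config$output_dir, "person_days.csv")

  models <- stage("exposure_models", fit_exposure_models(pd))
  ws <- stage("stabilized_weights", compute_stabilized_weights(models, pd))
  diag <- weight_diagnostics(ws)
  say("stabilized weights: mean %.3f, min-max %.2f-%.2f",
      diag$mean, diag$min, diag$max)
  paths$weights <- write_artifact(ws, config$output_dir, "weights.csv")
  paths$weight_diagnostics <- write_artifact(unclass(diag), config$output_dir,
                                             "weight_diagnostics.json")
  if (!is.null(config$output_dir)) {
    paths$weight_density_plot <- tryCatch({
      p <- file.path(config$output_dir, "weight_density.png")
      ggplot2::ggsave(p, plot_weight_density(ws), width = 6, height = 4,
                      dpi = 150)
      p
    }, error = function(e) NULL)
    paths$cu_distribution_plot <- tryCatch({
      p <- file.path(config$output_dir, "cu_distribution.png")
      ggplot2::ggsave(p, plot_cu_distribution(hd, thr), width = 7, height = 4,
                      dpi = 150)
      p
    }, error = function(e) NULL)
  }

  comparison <- stage("msm", compare_weighted_unweighted(
    pd, ws, exposure = config$exposure, cluster = config$cluster))
  fit_w <- attr(comparison, "weighted")
  fit_u <- attr(comparison, "unweighted")
  fit_short <- stage("msm_short_term",
                     fit_pooled_logistic(pd, exposure = "short", weights = ws,
                                         cluster = config$cluster))
  fit_trunc <- NULL
  if (!is.null(config$truncation)) {
    ws_t <- stage("truncate_weights",
                  truncate_weights(ws, config$truncation[1],
                                   config$truncation[2]))
    fit_trunc <- stage("msm_truncated",
                       fit_pooled_logistic(pd, exposure = config$exposure,
                                           weights = ws_t,
                                           cluster = config$cluster))
  }
  paths$msm_weighted <- write_artifact(msm_result_list(fit_w),
                                       config$output_dir, "msm_weighted.json")
  paths$msm_unweighted <- write_artifact(msm_result_list(fit_u),
                                         config$output_dir, "msm_unweighted.json")
  paths$msm_short_term <- write_artifact(msm_result_list(fit_short),
                                         config$output_dir, "msm_short_term.json")
  if (!is.null(fit_trunc))
    paths$msm_truncated <- write_artifact(msm_result_list(fit_trunc),
                                          config$output_dir, "msm_truncated.json")
  paths$comparison <- write_artifact(format_comparison_markdown(comparison),
                                     config$output_dir, "table2.md")

  t1 <- stage("table_one", table_one(filtered, config$weekday_of_day1))
  paths$table_one <- write_artifact(t1, config$output_dir, "table_one.csv")
  covsum <- stage("covariate_summary",
                  covariate_distribution_summary(hd, thr))
  paths$covariate_summary <- write_artifact(covsum, config$output_dir,
                                            "covariate_summary.csv")

  sens <- NULL
  if (!is.null(config$sensitivity_percentiles)) {
    sens <- stage("threshold_sensitivity", threshold_sensitivity(
      filtered, config$sensitivity_percentiles, config$year_length,
      config$weekday_of_day1, exposure = config$exposure,
      cluster = config$cluster, max_days = config$max_days))
    paths$sensitivity <- write_artifact(sens, config$output_dir,
                                        "sensitivity.csv")
  }

  eff <- function(fit) if (is.null(fit)) NULL else {
    e <- exposure_effect(fit)
    list(estimate = e$estimate, se = e$se, or = e$or,
         ci_lo = e$ci_lo, ci_hi = e$ci_hi)
  }
  manifest <- list(
    paths = paths[!vapply(paths, is.null, TRUE)],
    estimates = list(weighted = eff(fit_w), unweighted = eff(fit_u),
                     short_term = eff(fit_short), truncated = eff(fit_trunc)),
    weight_diagnostics = unclass(diag),
    exclusions = as.list(attr(filtered, "exclusions")),
    n_episodes = nrow(filtered), n_persondays = nrow(pd),
    n_deaths_14d = sum(pd$Y),
    seed = config$seed,
    package_version = as.character(packageVersion("occmsm"))
  )
  paths$manifest <- write_artifact(manifest, config$output_dir, "manifest.json")
  manifest$paths <- paths[!vapply(paths, is.null, TRUE)]
  invisible(manifest)
}
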