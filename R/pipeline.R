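# End-to-end orchestration: load or simulate -> exclusions -> split ->
# stack -> fit -> predict -> validate -> report, with a manifest that
# makes a run fully reproducible.

#' Pipeline run configuration
#'
#' @param visits_path,outcomes_path input CSVs (mutually exclusive with
#'   `simulation`).
#' @param simulation a [sim_config()] to generate the cohort instead of
#'   reading files.
#' @param split_fraction estimation-subcohort fraction (woman-level).
#' @param covariate_spec model terms for [fit_pc_cox()].
#' @param horizons prediction/validation horizons (years), sorted,
#'   positive; default the biennial grid 2..20.
#' @param subgroup_tau horizon of the subgroup calibration block.
#' @param output_dir run directory to create.
#' @param seed global seed; per-stage seeds are derived from it
#'   deterministically (`seed + 1009 * stage_offset`).
#' @return list of class `run_config`.
#' @export
run_config <- function(visits_path = NULL, outcomes_path = NULL,
                       simulation = NULL,
                       split_fraction = 0.6,
                       covariate_spec = c("age", "family_history",
                                          "bbd_category",
                                          "mammo_feature"),
                       horizons = seq(2, 20, by = 2),
                       subgroup_tau = 10,
                       output_dir = tempfile("screenrisk_run_"),
                       seed = 1L) {
  if (is.null(simulation) &&
      (is.null(visits_path) || is.null(outcomes_path)))
    sr_stop("either input CSV paths or a simulation config is required",
            "config", "ESPEC")
  if (any(horizons <= 0) || is.unsorted(horizons))
    sr_stop("horizons must be positive and sorted", "config", "ESPEC")
  structure(list(visits_path = visits_path,
                 outcomes_path = outcomes_path,
                 simulation = simulation,
                 split_fraction = split_fraction,
                 covariate_spec = covariate_spec,
                 horizons = horizons, subgroup_tau = subgroup_tau,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full risk-model pipeline
#'
#' Executes load/simulate, exclusions, woman-level 60/40 split, record
#' stacking, the partly conditional Cox fit on the estimation side,
#' baseline-landmark risk prediction, calibration and discrimination on
#' the validation side, and writes publication-style tables
#' (`table1.csv` baseline characteristics, `table2.csv` hazard ratios,
#' `table3.csv` per-horizon E/O + AUC, `table4.csv` subgroup
#' calibration, `fig1_bins.csv` risk distributions), fit artifacts and
#' a JSON manifest into the run directory.
#'
#' @param config a [run_config()], or the path of a `manifest.json`
#'   from a previous run (the run is then reproduced).
#' @return list with the run directory, the fit, and the report tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- config_from_manifest(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  # stage: load or simulate
  if (!is.null(config$simulation)) {
    sim <- simulate_cohort(config$simulation)
    cohort <- sim$cohort
  } else {
    cohort <- load_cohort(config$visits_path, config$outcomes_path)
  }

  cohort <- apply_exclusions(cohort)
  parts <- split_cohort(cohort, fraction = config$split_fraction,
                        seed = derive_seed(config$seed, 1L))

  stacked_est <- build_stacked(parts$estimation)
  fit <- fit_pc_cox(stacked_est, covariate_spec = config$covariate_spec)

  table1 <- describe_cohort(cohort)
  table2 <- hazard_ratio_table(fit, stacked_est)

  calib <- list(); disc <- list(); bins <- list()
  val <- parts$validation
  base_risks <- list()
  for (tau in config$horizons) {
    risks <- baseline_risks(fit, val, tau)
    base_risks[[as.character(tau)]] <- risks
    obs <- observed_risk_km(val, tau)
    calib[[as.character(tau)]] <-
      eo_ratio(mean(risks), obs$incidence, obs$O, tau = tau)
    disc[[as.character(tau)]] <-
      auc_at_horizon(risks, val$outcomes, tau)
  }
  for (tau in intersect(c(2, 10, 20), config$horizons)) {
    b <- risk_distribution(base_risks[[as.character(tau)]],
                           horizon = tau)
    b$horizon <- tau
    bins[[as.character(tau)]] <- b
  }
  sub <- do.call(rbind, lapply(
    c("age_band", "family_history", "bbd_category", "mammo_feature"),
    function(gr) subgroup_calibration(val, fit, tau = config$subgroup_tau,
                                      grouping = gr)))
  overall <- calib[[as.character(config$subgroup_tau)]]
  overall$grouping <- "overall"
  table4 <- rbind(overall, sub)

  report <- validation_report(do.call(rbind, calib), do.call(rbind, disc),
                              subgroups = table4,
                              bins = do.call(rbind, bins),
                              dir = config$output_dir)

  utils::write.csv(as.data.frame(table1),
                   file.path(config$output_dir, "table1.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(table2),
                   file.path(config$output_dir, "table2.csv"),
                   row.names = FALSE)
  write_fit(fit, file.path(config$output_dir, "fit.json"))

  manifest <- list(
    package = "screenrisk",
    version = as.character(utils::packageVersion("screenrisk")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    split_fraction = config$split_fraction,
    covariate_spec = config$covariate_spec,
    horizons = config$horizons,
    subgroup_tau = config$subgroup_tau,
    inputs = if (is.null(config$simulation))
      list(visits_path = config$visits_path,
           outcomes_path = config$outcomes_path)
    else list(simulation = lapply(unclass(config$simulation), function(x)
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)),
    counts = list(
      women = nrow(cohort$outcomes),
      visits = nrow(cohort$visits),
      events = sum(cohort$outcomes$event),
      estimation_women = nrow(parts$estimation$outcomes),
      validation_women = nrow(parts$validation$outcomes),
      stacked_records = nrow(stacked_est)),
    exclusions = as.list(cohort$exclusion_log))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(output_dir = config$output_dir, fit = fit, cohort = cohort,
       split = parts, table1 = table1, table2 = table2,
       table3 = report$table3, table4 = report$table4,
       fig1_bins = report$fig1_bins, manifest = manifest)
}

# Rebuild a run_config from a manifest written by run_pipeline().
config_from_manifest <- function(path) {
  if (!file.exists(path))
    sr_stop(paste("manifest not found:", path), "load", "ENOENT")
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  simulation <- NULL
  if (!is.null(m$inputs$simulation)) {
    raw <- m$inputs$simulation
    for (nm in c("entry_age_weights", "bbd_baseline_probs",
                 "bbd_progression", "feature_probs", "true_log_hr"))
      raw[[nm]] <- unlist(raw[[nm]])
    simulation <- do.call(sim_config, raw)
  }
  run_config(visits_path = m$inputs$visits_path,
             outcomes_path = m$inputs$outcomes_path,
             simulation = simulation,
             split_fraction = m$split_fraction,
             covariate_spec = m$covariate_spec,
             horizons = m$horizons,
             subgroup_tau = m$subgroup_tau,
             output_dir = tempfile("screenrisk_rerun_"),
             seed = m$seed)
}
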