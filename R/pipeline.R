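# End-to-end orchestration: simulate (or read) a trial, run the
# intention-to-treat / per-protocol outcome analyses, build QALYs and
# costs, fit the Bayesian cost-effectiveness model, check the design, and
# write a report bundle (CSV tables, plots, JSON manifest). Identical
# configuration and seeds give byte-identical tables.

#' Pipeline run configuration
#'
#' @param simulation a [simulation_config()], or `NULL` when reading from
#'   `input_csv`.
#' @param input_csv participant-level CSV path (ignored when `simulation`
#'   is given).
#' @param outcome primary outcome label (default `"mcs"`).
#' @param populations analysis populations to run: subset of
#'   `"ITT_LOCF"`, `"ITT_MI"`, `"per_protocol"`.
#' @param m number of multiple imputations for the sensitivity analysis.
#' @param intervention_cost_per_year,attribution see [aggregate_costs()].
#' @param cea a [cea_model_config()]; pass smaller `burn_in`/`kept` for
#'   quick runs.
#' @param design a [design_spec()]; the design check recomputes the
#'   per-group sample size and simulated power.
#' @param power_replicates simulated trials in the design check.
#' @param seed master seed for the imputation and power streams.
#' @param out_dir output directory for the report bundle.
#' @param make_plots write the acceptability-curve and plane PNGs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulation = simulation_config(),
                       input_csv = NULL,
                       outcome = "mcs",
                       populations = c("ITT_LOCF", "ITT_MI", "per_protocol"),
                       m = 5L,
                       intervention_cost_per_year = 15,
                       attribution = "full",
                       cea = cea_model_config(),
                       design = design_spec(),
                       power_replicates = 2000L,
                       seed = 1L,
                       out_dir = tempfile("beamcea_run_"),
                       make_plots = TRUE) {
  abort_if(is.null(simulation) && is.null(input_csv),
           "either a simulation config or an input CSV is required")
  abort_if(!is.null(input_csv) && is.null(simulation) && !file.exists(input_csv),
           "input file not found: %s", input_csv)
  bad <- setdiff(populations, c("ITT_LOCF", "ITT_MI", "per_protocol"))
  abort_if(length(bad) > 0, "unknown population(s): %s",
           paste(bad, collapse = ", "))
  structure(list(simulation = simulation, input_csv = input_csv,
                 outcome = outcome, populations = populations, m = m,
                 intervention_cost_per_year = intervention_cost_per_year,
                 attribution = attribution, cea = cea, design = design,
                 power_replicates = power_replicates,
                 seed = seed, out_dir = out_dir, make_plots = make_plots),
            class = "run_config")
}

#' Adherence and retention summary
#'
#' Medians and interquartile ranges of completed sessions and platform
#' minutes in the intervention arm, the implied adherence percentages
#' (structured sessions out of 24, education sessions out of 12), minutes
#' per week over the 12-week structured phase, and per-arm retention.
#' Report percentages are rounded half-up to whole percent, so a median of
#' 15/24 sessions prints as 63% and 105/173 retention as 61%.
#'
#' @param dataset a [trial_dataset()].
#' @return A list of class `adherence_summary`.
#' @export
adherence_summary <- function(dataset) {
  validate_trial_dataset(dataset)
  iv <- as.data.frame(dataset)[dataset$arm == "intervention", ]
  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                   names = FALSE, type = 2)
  qs <- q(iv$sessions_structured)
  qe <- q(iv$sessions_education)
  qm <- q(iv$minutes_structured)
  retention <- vapply(ARM_LEVELS, function(a) {
    rows <- dataset$arm == a
    round_half_up(100 * sum(dataset$completed_week24[rows]) / sum(rows))
  }, 0)
  structure(list(
    sessions_structured = list(median = qs[2], iqr = qs[c(1, 3)]),
    sessions_education = list(median = qe[2], iqr = qe[c(1, 3)]),
    minutes_structured = list(median = qm[2], iqr = qm[c(1, 3)]),
    adherence_structured_pct = round_half_up(100 * qs / 24),
    adherence_education_pct = round_half_up(100 * qe / 12),
    minutes_per_week = round_half_up(qm[2] / 12),
    retention_pct = retention),
    class = "adherence_summary")
}

#' @export
print.adherence_summary <- function(x, ...) {
  cat(sprintf("Structured sessions: median %g (IQR %g-%g) of 24 = %d%% adherence\n",
              x$sessions_structured$median, x$sessions_structured$iqr[1],
              x$sessions_structured$iqr[2], x$adherence_structured_pct[2]))
  cat(sprintf("Education sessions: median %g (IQR %g-%g) of 12 = %d%% adherence\n",
              x$sessions_education$median, x$sessions_education$iqr[1],
              x$sessions_education$iqr[2], x$adherence_education_pct[2]))
  cat(sprintf("Structured minutes: median %g = %d min/wk over 12 weeks\n",
              x$minutes_structured$median, x$minutes_per_week))
  cat(sprintf("Retention: %d%% intervention, %d%% control\n",
              x$retention_pct[["intervention"]], x$retention_pct[["control"]]))
  invisible(x)
}

#' Plot the cost-effectiveness acceptability curve
#'
#' @param curve a [ceac()] result.
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
plot_ceac <- function(curve, path) {
  stopifnot(inherits(curve, "ceac_curve"))
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  graphics::plot(curve$wtp, curve$probability_cost_effective, type = "b",
                 pch = 19, ylim = c(0, 1),
                 xlab = "Willingness to pay (GBP per QALY)",
                 ylab = "Probability cost-effective",
                 main = "Cost-effectiveness acceptability curve")
  graphics::abline(v = c(20000, 30000), lty = 3)
  invisible(path)
}

#' Plot the cost-effectiveness plane with its 95% ellipse
#'
#' @param posterior a [fit_cea()] result.
#' @param path PNG path.
#' @param max_points number of posterior draws scattered.
#' @return `path`, invisibly.
#' @export
plot_ce_plane <- function(posterior, path, max_points = 2000L) {
  stopifnot(inherits(posterior, "cea_posterior"))
  plane <- ce_plane(posterior)
  d <- posterior$draws
  idx <- seq(1, nrow(d), length.out = min(max_points, nrow(d)))
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  graphics::plot(d$delta_qaly[idx], d$delta_cost[idx], pch = ".",
                 col = "grey40",
                 xlab = "Incremental QALYs",
                 ylab = "Incremental cost (GBP)",
                 main = "Cost-effectiveness plane")
  graphics::lines(plane$ellipse[, "delta_qaly"], plane$ellipse[, "delta_cost"],
                  lwd = 2)
  graphics::abline(h = 0, v = 0, lty = 2)
  graphics::points(plane$center[1], plane$center[2], pch = 4, cex = 1.5)
  invisible(path)
}

write_table <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE, na = "",
                     qmethod = "double")
  path
}

#' Run the full within-trial evaluation pipeline
#'
#' Executes simulate (or read) -> outcome analyses -> QALY and cost
#' construction -> Bayesian cost-effectiveness model -> design check, and
#' writes a report bundle: `trial.csv` (when simulated), `outcomes.csv`
#' (one row per analysis population), `adherence.csv`, `cea_summary.csv`,
#' `ceac.csv`, optional `ceac.png` / `ce_plane.png`, and `manifest.json`
#' recording seeds, configuration hash, package version and per-stage
#' record counts. Reruns with the same configuration produce byte-identical
#' tables.
#'
#' @param config a [run_config()].
#' @return The bundle as a list (invisibly returns paths in `$files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log <- list()

  # --- data stage
  if (!is.null(config$simulation)) {
    dataset <- generate_trial(config$simulation)
    dataset <- apply_dropout(dataset, config$simulation)
    files["trial"] <- write_trial_csv(dataset,
                                      file.path(config$out_dir, "trial.csv"))
  } else {
    abort_if(!file.exists(config$input_csv),
             "stage data: input file not found: %s", config$input_csv)
    dataset <- read_trial_csv(config$input_csv)
  }
  log$n_randomized <- nrow(dataset)

  # --- outcome stage
  rows <- list()
  for (pop in config$populations) {
    est <- switch(pop,
      ITT_LOCF = ancova_fit(locf_impute(dataset, config$outcome),
                            config$outcome, population = "ITT_LOCF"),
      ITT_MI = {
        sets <- mi_impute(dataset, config$outcome, m = config$m,
                          seed = config$seed)
        rubin_pool(lapply(sets, ancova_fit, outcome = config$outcome,
                          population = "ITT_MI"))
      },
      per_protocol = ancova_fit(per_protocol_filter(dataset, config$outcome),
                                config$outcome, population = "per_protocol"))
    rows[[pop]] <- data.frame(
      population = pop, outcome = config$outcome,
      effect = est$effect,
      se = if (inherits(est, "pooled_estimate")) sqrt(est$total_var) else est$se,
      ci_low = est$ci_low, ci_high = est$ci_high, p_value = est$p_value,
      n = if (inherits(est, "pooled_estimate")) NA_integer_ else est$n_used)
  }
  outcomes_tbl <- do.call(rbind, rows)
  files["outcomes"] <- write_table(outcomes_tbl,
                                   file.path(config$out_dir, "outcomes.csv"))
  log$populations <- config$populations

  # --- adherence
  adh <- adherence_summary(dataset)
  adh_tbl <- data.frame(
    measure = c("sessions_structured_median", "adherence_structured_pct",
                "minutes_per_week", "retention_intervention_pct",
                "retention_control_pct"),
    value = c(adh$sessions_structured$median, adh$adherence_structured_pct[2],
              adh$minutes_per_week, adh$retention_pct[["intervention"]],
              adh$retention_pct[["control"]]))
  files["adherence"] <- write_table(adh_tbl,
                                    file.path(config$out_dir, "adherence.csv"))

  # --- economics stage: utilities LOCF'd (intention-to-treat base case),
  # cost components LVCF'd, then only participants with an analyzable
  # utility profile enter the model
  econ_data <- locf_impute(dataset, "eq5d")
  econ_data <- lvcf_costs(econ_data)
  qalys <- compute_qalys(econ_data)
  costs <- aggregate_costs(econ_data, config$intervention_cost_per_year,
                           config$attribution)
  econ <- merge(qalys, costs[c("participant_id", "baseline_cost",
                               "trial_cost")], by = "participant_id")
  base_u <- econ_data$eq5d_m0[match(econ$participant_id,
                                    econ_data$participant_id)]
  log$n_econ <- nrow(econ)
  log$n_lvcf_cells <- sum(attr(econ_data, "imputed"))

  # --- cost-effectiveness stage
  posterior <- fit_cea(econ$trial_cost, econ$qaly, econ$arm,
                       econ$baseline_cost, base_u, config$cea)
  summ <- cea_summary(posterior)
  cea_tbl <- data.frame(
    quantity = c("mean_cost_saving", "cost_saving_ci_low",
                 "cost_saving_ci_high", "mean_delta_qaly",
                 "delta_qaly_ci_low", "delta_qaly_ci_high", "icer",
                 paste0("p_ce_at_", names(summ$p_ce_at))),
    value = c(summ$mean_cost_saving, summ$cost_saving_ci,
              summ$mean_delta_qaly, summ$delta_qaly_ci,
              summ$icer$value, unname(summ$p_ce_at)))
  files["cea_summary"] <- write_table(cea_tbl,
                                      file.path(config$out_dir,
                                                "cea_summary.csv"))
  files["ceac"] <- write_table(as.data.frame(ceac(posterior)),
                               file.path(config$out_dir, "ceac.csv"))
  if (config$make_plots) {
    files["ceac_plot"] <- plot_ceac(ceac(posterior),
                                    file.path(config$out_dir, "ceac.png"))
    files["plane_plot"] <- plot_ce_plane(posterior,
                                         file.path(config$out_dir,
                                                   "ce_plane.png"))
  }

  # --- design check
  n_design <- sample_size_change_score(config$design)
  pw <- simulate_power(config$design, n_design,
                       replicates = config$power_replicates,
                       seed = config$seed)
  design_tbl <- data.frame(
    quantity = c("n_per_group", "n_inflated", "simulated_power"),
    value = c(n_design,
              inflate_for_dropout(n_design, config$design$dropout_allowance),
              pw$power))
  files["design"] <- write_table(design_tbl,
                                 file.path(config$out_dir, "design.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("beamcea")),
    seed = config$seed,
    simulation_seed = if (!is.null(config$simulation))
      config$simulation$seed else NULL,
    cea_seed = config$cea$seed,
    config_hash = sum(utf8ToInt(paste(
      utils::capture.output(utils::str(config)), collapse = ""))),
    stages = log,
    converged = summ$converged,
    files = as.list(files))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  files["manifest"] <- manifest_path

  invisible(list(dataset = dataset, outcomes = outcomes_tbl,
                 adherence = adh, posterior = posterior, summary = summ,
                 design = design_tbl, files = files))
}
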