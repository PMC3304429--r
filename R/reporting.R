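#' Base-case outcome report
#'
#' Runs both arms and lays the comparison out with one row per outcome and
#' columns for SLNB, ALND and their difference at 5 years and at the horizon
#' (per 1000 patients; monetary outcomes also per patient), plus the
#' dominance classification.
#'
#' @param params,costs,settings Model objects.
#' @param out_dir Optional directory; if given, the table is written to
#'   `base_case.csv` (and a run manifest if `manifest = TRUE`).
#' @param manifest Write `manifest.json` alongside the outputs.
#' @param seed Recorded in the manifest (the cohort model itself is
#'   deterministic).
#' @return A list with `table` (the wide report), `comparison` (the
#'   [compare()] result) and `classification`.
#' @export
base_case_report <- function(params = parameter_set(), costs = cost_set(),
                             settings = model_settings(), out_dir = NULL,
                             manifest = FALSE, seed = NULL) {
  cmp <- compare(run_cohort("SLNB", params, costs, settings),
                 run_cohort("ALND", params, costs, settings))
  horizons <- unique(cmp$horizon)
  wide <- NULL
  for (h in horizons) {
    sub <- cmp[cmp$horizon == h, c("measure", "slnb", "alnd", "difference")]
    names(sub)[2:4] <- paste0(c("slnb_", "alnd_", "difference_"), h, "y")
    wide <- if (is.null(wide)) sub else merge(wide, sub, by = "measure", sort = FALSE)
  }
  per_patient <- cmp[grepl("^cost_", cmp$measure), ]
  per_patient$slnb <- per_patient$slnb / 1000
  per_patient$alnd <- per_patient$alnd / 1000
  per_patient$difference <- per_patient$difference / 1000
  cls <- attr(cmp, "classification")
  fav <- vapply(cls, function(x) switch(x, "SLNB dominant" = "Favours SLNB",
                                        "ALND dominant" = "Favours ALND", x),
                character(1))
  out <- list(table = wide, comparison = cmp, cost_per_patient = per_patient,
              classification = cls, favours = fav)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(out_dir, "base_case.csv")
    utils::write.csv(wide, path, row.names = FALSE)
    if (manifest)
      write_manifest("base-case", out_dir, outputs = "base_case.csv",
                     seed = seed, settings = settings)
  }
  out
}

# Default threshold search specification: the model inputs for which a
# preferred-strategy switch exists within a plausible search interval.
default_threshold_specs <- function() {
  list(
    list(parameter = "p_node_positive", outcome = "incremental_QALY",
         bounds = c(0.05, 0.80)),
    list(parameter = "cum5_axillary_recur_given_fn", outcome = "incremental_QALY",
         bounds = c(0.001, 0.60)),
    list(parameter = "p_slnb_fn", outcome = "incremental_QALY",
         bounds = c(0, 0.30)),
    list(parameter = "p_lymph_alnd", outcome = "incremental_QALY",
         bounds = c(0.119, 0.25)),
    list(parameter = "lymphoedema_disutility", outcome = "incremental_QALY",
         bounds = c(0, 0.05)),
    list(parameter = "c_slnb_pos_then_alnd", outcome = "incremental_cost",
         bounds = c(7771.28, 80000)),
    list(parameter = "c_slnb_neg", outcome = "incremental_cost",
         bounds = c(4206.38, 80000)),
    list(parameter = "c_alnd", outcome = "incremental_cost",
         bounds = c(500, 5576.45)),
    list(parameter = "p_node_positive", outcome = "incremental_cost",
         bounds = c(0.05, 0.80))
  )
}

#' One-way threshold report
#'
#' Runs [one_way_threshold()] for the standard set of inputs with
#' effectiveness or cost thresholds (or a custom specification) and collects
#' the results. Non-converged searches are reported, not dropped. For the
#' three surgical-cost thresholds the bundle value including the arm's
#' adjuvant therapy cost is also reported, since staging and adjuvant costs
#' are accrued together upfront.
#'
#' @param specs A list of lists with `parameter`, `outcome`, `bounds`;
#'   defaults to [default_threshold_specs()].
#' @param params,costs,settings Model objects.
#' @param out_dir Optional output directory (`thresholds.csv`).
#' @return A data.frame with one row per search: `parameter`, `outcome`,
#'   `threshold`, `threshold_with_adjuvant` (surgical costs only),
#'   `direction`, `converged`, `lower`, `upper`.
#' @export
thresholds_report <- function(specs = default_threshold_specs(),
                              params = parameter_set(), costs = cost_set(),
                              settings = model_settings(), out_dir = NULL) {
  rows <- lapply(specs, function(s) {
    th <- one_way_threshold(s$parameter, s$outcome, s$bounds,
                            params = params, costs = costs, settings = settings)
    adj <- NA_real_
    if (s$parameter %in% c("c_slnb_pos_then_alnd", "c_slnb_neg") && th$converged)
      adj <- th$threshold + arm_adjuvant_cost(costs, "SLNB",
                                              settings$differential_adjuvant_uptake)
    if (s$parameter == "c_alnd" && th$converged)
      adj <- th$threshold + arm_adjuvant_cost(costs, "ALND",
                                              settings$differential_adjuvant_uptake)
    data.frame(parameter = s$parameter, outcome = s$outcome,
               threshold = th$threshold, threshold_with_adjuvant = adj,
               direction = th$direction, converged = th$converged,
               lower = s$bounds[1], upper = s$bounds[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "thresholds.csv"), row.names = FALSE)
  }
  out
}

#' Cohort-engine versus microsimulation validation report
#'
#' Runs the cohort model (with and without half-cycle correction) and the
#' independent microsimulation for both arms, and reports per-1000 outcomes
#' side by side with Monte-Carlo standard errors and z-scores of the
#' oracle-versus-engine differences. Utilities and annual costs in the
#' microsimulation are accrued without half-cycle correction, so its means
#' are estimates of the `half_cycle_correction = FALSE` engine values.
#'
#' @param n_patients Patients per arm.
#' @param seed Integer seed.
#' @param params,costs,settings Model objects.
#' @param out_dir Optional output directory (`validation.csv`).
#' @return A data.frame with one row per arm and measure: engine values with
#'   and without half-cycle correction, microsimulation mean and SE, and
#'   `z_no_hcc` = (mean - engine_no_hcc) / SE.
#' @export
validate_report <- function(n_patients = 20000, seed = 1, params = parameter_set(),
                            costs = cost_set(), settings = model_settings(),
                            out_dir = NULL) {
  st_no_hcc <- settings
  st_no_hcc$half_cycle_correction <- FALSE
  H <- settings$horizon
  rows <- lapply(c("SLNB", "ALND"), function(arm) {
    eng <- run_cohort(arm, params, costs, settings)$measures
    eng0 <- run_cohort(arm, params, costs, st_no_hcc)$measures
    sim <- simulate_arm(arm, n_patients, seed, params, costs, settings)$summary
    m <- merge(sim, eng[eng$horizon == H, ], by = "measure")
    m <- merge(m, eng0[eng0$horizon == H, ], by = "measure",
               suffixes = c("_hcc", "_no_hcc"))
    data.frame(arm = arm, measure = m$measure,
               engine_hcc = m$value_hcc, engine_no_hcc = m$value_no_hcc,
               microsim_mean = m$mean_per_1000, microsim_se = m$se_per_1000,
               z_no_hcc = (m$mean_per_1000 - m$value_no_hcc) /
                 ifelse(m$se_per_1000 > 0, m$se_per_1000, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "validation.csv"), row.names = FALSE)
  }
  out
}

#' Write a run manifest
#'
#' Records the command, configuration, seed, package version, timestamp and
#' output files of a run as JSON, written atomically (temp file + rename)
#' alongside the outputs.
#'
#' @param command Command or analysis name.
#' @param out_dir Output directory.
#' @param outputs Character vector of output file names in `out_dir`.
#' @param config Optional path to the configuration file used.
#' @param seed Optional seed.
#' @param settings Optional [model_settings()] to embed.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(command, out_dir, outputs, config = NULL,
                           seed = NULL, settings = NULL) {
  man <- list(command = command,
              config = if (is.null(config)) NA else config,
              seed = if (is.null(seed)) NA else seed,
              package_version = as.character(utils::packageVersion("axstage")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              outputs = as.list(outputs))
  if (!is.null(settings)) man$settings <- unclass(settings)
  path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Export the cohort trace as a tidy table
#'
#' @param arm_result An `ax_arm_result` from [run_cohort()].
#' @param file Optional CSV path.
#' @return A data.frame: `pathway`, `nodal_status`, `cycle`, `state`,
#'   `occupancy`.
#' @export
export_trace <- function(arm_result, file = NULL) {
  tr <- arm_result$trace
  if (!is.null(file)) utils::write.csv(tr, file, row.names = FALSE)
  tr
}
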