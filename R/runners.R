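# Reproducible run entry points behind the command-line script
# (inst/cli/vhi.R). Every run writes the tables it produced plus a JSON
# manifest (config, seed, versions) sufficient to recreate the outputs.

ensure_outdir <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  invisible(out_dir)
}

write_manifest <- function(out_dir, subcommand, config, seed) {
  manifest <- list(
    subcommand = subcommand,
    seed = seed,
    config = config,
    package = "vhisim",
    package_version = as.character(utils::packageVersion("vhisim")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run a cohort simulation and write its outputs
#'
#' Simulates a virtual cohort ([simulate_cohort()]), writes the trial table
#' (`cohort.csv` + JSON config sidecar), a per-condition summary and a
#' manifest; optionally full trial traces for the first participant.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n_sync,n_async,trials_per_condition As in [simulate_cohort()].
#' @param params A [vhi_params()] object.
#' @param noise Observation noise on/off.
#' @param write_traces Also write the three condition traces of participant 1?
#' @return The trial table, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1, n_sync = 10, n_async = 10,
                         trials_per_condition = 4, params = vhi_params(),
                         noise = TRUE, write_traces = FALSE) {
  ensure_outdir(out_dir)
  config <- list(n_sync = n_sync, n_async = n_async,
                 trials_per_condition = trials_per_condition,
                 noise = noise, params = unclass(params))
  tab <- simulate_cohort(n_sync, n_async, trials_per_condition, seed,
                         params, noise)
  write_trial_table(tab, file.path(out_dir, "cohort.csv"), config)
  utils::write.csv(as.data.frame(
    tab |> dplyr::group_by(.data$group, .data$condition) |>
      dplyr::summarise(sd_force_N = sd(.data$mean_force_N),
                       mean_force_N = mean(.data$mean_force_N),
                       .groups = "drop") |>
      dplyr::select("group", "condition", "mean_force_N", "sd_force_N")),
    file.path(out_dir, "summary.csv"), row.names = FALSE)
  if (isTRUE(write_traces)) {
    prof <- sample_participants(1, "synchronous",
                                seed = derive_seed(seed, "sync"))
    for (cond in names(condition_offsets())) {
      tr <- simulate_trial(prof[1, ], condition_offsets()[[cond]], params,
                           noise, seed = derive_seed(seed, 1, cond, 1))
      write_trial(tr, file.path(out_dir, paste0("trace_", cond, ".csv")))
    }
  }
  write_manifest(out_dir, "simulate", config, seed)
  invisible(tab)
}

#' Analyze a trial table and write the statistics report
#'
#' Reads a TrialTable CSV, runs [analyze_forces()], and writes `stats.json`
#' (tidy ANOVA + post-hoc tables), a plain-text report, optional figures and
#' a manifest.
#'
#' @param table_path Path to a TrialTable CSV (schema of
#'   [read_trial_table()]).
#' @param out_dir Output directory.
#' @param col_map Optional column mapping passed to [read_trial_table()].
#' @param write_figures Write the summary figure as PDF?
#' @return The `vhi_stats` object, invisibly.
#' @export
run_analyze <- function(table_path, out_dir, col_map = NULL,
                        write_figures = FALSE) {
  ensure_outdir(out_dir)
  tab <- read_trial_table(table_path, col_map)
  stats <- analyze_forces(tab)
  jsonlite::write_json(list(
    summary = stats$summary,
    anova = stats$anova$table,
    posthoc = stats$posthoc$table
  ), file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "rows", pretty = TRUE)
  con <- file(file.path(out_dir, "report.txt"), "w")
  sink(con); print(stats); sink()
  close(con)
  if (isTRUE(write_figures)) {
    ggplot2::ggsave(file.path(out_dir, "force_summary.pdf"),
                    plot_force_summary(tab, by_group = "group" %in% names(tab) &&
                                         length(unique(tab$group)) > 1),
                    width = 6, height = 4)
  }
  write_manifest(out_dir, "analyze", list(table_path = table_path), seed = NA)
  invisible(stats)
}

#' Run a causality-parameter sweep and write its outputs
#'
#' @param out_dir Output directory.
#' @param kappas Causality values in `[0, 1]`.
#' @param n_per_kappa,trials_per_condition,seed,params,noise As in
#'   [kappa_sweep()].
#' @param write_figures Write the sweep figure as PDF?
#' @return The per-(kappa, condition) summary tibble, invisibly.
#' @export
run_sweep <- function(out_dir, kappas = c(0, 0.3, 0.6, 0.9),
                      n_per_kappa = 10, trials_per_condition = 4, seed = 1,
                      params = vhi_params(), noise = TRUE,
                      write_figures = FALSE) {
  ensure_outdir(out_dir)
  config <- list(kappas = kappas, n_per_kappa = n_per_kappa,
                 trials_per_condition = trials_per_condition, noise = noise)
  tab <- kappa_sweep(kappas, n_per_kappa, trials_per_condition, seed,
                     params, noise)
  smry <- summarize_sweep(tab)
  write_trial_table(tab, file.path(out_dir, "sweep.csv"), config)
  utils::write.csv(as.data.frame(smry), file.path(out_dir, "sweep_summary.csv"),
                   row.names = FALSE)
  if (isTRUE(write_figures))
    ggplot2::ggsave(file.path(out_dir, "kappa_sweep.pdf"),
                    plot_kappa_sweep(smry), width = 6, height = 4)
  write_manifest(out_dir, "sweep", config, seed)
  invisible(smry)
}

#' Write an experimental schedule to CSV
#'
#' @param out_dir Output directory.
#' @param n_participants,seed As in [generate_schedule()].
#' @return The schedule tibble, invisibly.
#' @export
run_design <- function(out_dir, n_participants = 14, seed = 1) {
  ensure_outdir(out_dir)
  sched <- generate_schedule(n_participants, seed)
  utils::write.csv(as.data.frame(sched), file.path(out_dir, "schedule.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "design", list(n_participants = n_participants),
                 seed)
  invisible(sched)
}
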