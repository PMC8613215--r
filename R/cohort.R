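#' Sample virtual participants
#'
#' Draws participant-level variability from the distributions used for the
#' simulated cohorts: initial proprioceptive variance
#' `sigma_sp2 ~ N(1, 0.5)` (SD; truncated below at 0.05), localization bias
#' `b ~ N(0, 4.2794)` cm and forearm length `L ~ N(44.7208, 2.4807)` cm, the
#' latter two taken from human rubber-hand-illusion measurements. The
#' causality weight is 1 for the synchronous group and 0.3 for the
#' asynchronous one unless overridden.
#'
#' @param n Number of participants.
#' @param group `"synchronous"` or `"asynchronous"`.
#' @param seed Optional integer seed.
#' @param kappa Optional causality value overriding the group default.
#' @param pid_offset Added to the 1-based participant ids (to keep ids unique
#'   across groups).
#' @return A tibble with columns `pid`, `group`, `sigma_sp2`, `b`, `L`,
#'   `kappa`.
#' @examples
#' sample_participants(3, "synchronous", seed = 1)
#' @export
sample_participants <- function(n, group = c("synchronous", "asynchronous"),
                                seed = NULL, kappa = NULL, pid_offset = 0) {
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(kappa)) kappa <- if (group == "synchronous") 1 else 0.3
  sigma_sp2 <- vapply(seq_len(max(n, 0)), function(i) {
    repeat {
      x <- rnorm(1, 1, 0.5)
      if (x > 0.05) return(x)
    }
  }, numeric(1))
  tibble::tibble(
    pid = seq_len(n) + pid_offset,
    group = group,
    sigma_sp2 = sigma_sp2,
    b = rnorm(n, 0, 4.2794),
    L = abs(rnorm(n, 44.7208, 2.4807)),
    kappa = kappa
  )
}

condition_offsets <- function() c(Left = -15, Center = 0, Right = 15)

# Run all trials for one participant profile and return TrialTable rows.
participant_trials <- function(profile, trials_per_condition, seed,
                               params, noise, window = c(10, 15)) {
  conds <- condition_offsets()
  purrr::map_dfr(names(conds), function(cond) {
    purrr::map_dfr(seq_len(trials_per_condition), function(tr) {
      s <- derive_seed(seed, profile$pid, cond, tr)
      res <- simulate_trial(profile, offset_cm = conds[[cond]],
                            params = params, noise = noise, seed = s)
      mf <- window_mean(res, window[1], window[2])
      tibble::tibble(
        pid = profile$pid, group = profile$group, kappa = profile$kappa,
        block = (tr - 1) %/% 4 + 1, trial = tr, condition = cond,
        mean_force_N = mf
      )
    })
  })
}

#' Simulate a full virtual cohort
#'
#' Samples synchronous and asynchronous participants, runs every trial of the
#' requested design (Left/Center/Right, `trials_per_condition` each) and
#' records the windowed (10-15 s) mean lateral force per trial, in the same
#' table schema the human experiment produces.
#'
#' @param n_sync,n_async Number of participants per stimulation group.
#' @param trials_per_condition Trials per condition per participant.
#' @param seed Integer master seed; participant sampling and all per-trial
#'   observation-noise streams are derived from it.
#' @param params Base [vhi_params()]; participant fields are overridden per
#'   profile.
#' @param noise Logical; per-sample observation noise in each trial.
#' @param window Analysis window `(t0, t1)` in s for the per-trial mean.
#' @return A tibble (TrialTable) with columns `pid`, `group`, `kappa`,
#'   `block`, `trial`, `condition`, `mean_force_N`.
#' @examples
#' \donttest{
#' tab <- simulate_cohort(2, 2, trials_per_condition = 1, seed = 1)
#' }
#' @export
simulate_cohort <- function(n_sync = 10, n_async = 10,
                            trials_per_condition = 4, seed = 1,
                            params = vhi_params(), noise = TRUE,
                            window = c(10, 15)) {
  stopifnot(n_sync >= 1, n_async >= 1, trials_per_condition >= 1)
  profiles <- dplyr::bind_rows(
    sample_participants(n_sync, "synchronous", seed = derive_seed(seed, "sync")),
    sample_participants(n_async, "asynchronous",
                        seed = derive_seed(seed, "async"), pid_offset = n_sync)
  )
  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    participant_trials(profiles[i, ], trials_per_condition, seed, params,
                       noise, window)
  })
}

#' Sweep the causality parameter over a fixed cohort
#'
#' Runs the same sampled participants (identical profiles and observation
#' noise streams) under each causality value, so comparisons across `kappa`
#' are paired. This replicates the synchrony study: forces shrink as the
#' believed visuo-tactile causal link weakens, vanishing (up to noise) at
#' `kappa = 0`.
#'
#' @param kappas Numeric vector of causality values in `[0, 1]`.
#' @param n_per_kappa Participants simulated per value.
#' @param trials_per_condition Trials per condition per participant.
#' @param seed Integer master seed.
#' @param params,noise,window As in [simulate_cohort()].
#' @return A TrialTable tibble with a `kappa` column (group is labelled
#'   `"sweep"`).
#' @export
kappa_sweep <- function(kappas = c(0, 0.3, 0.6, 0.9), n_per_kappa = 10,
                        trials_per_condition = 4, seed = 1,
                        params = vhi_params(), noise = TRUE,
                        window = c(10, 15)) {
  if (any(kappas < 0 | kappas > 1))
    stop("all `kappas` must lie in [0, 1]", call. = FALSE)
  profiles <- sample_participants(n_per_kappa, "synchronous",
                                  seed = derive_seed(seed, "sweep"))
  profiles$group <- "sweep"
  purrr::map_dfr(kappas, function(k) {
    purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
      pr <- profiles[i, ]
      pr$kappa <- k
      participant_trials(pr, trials_per_condition, seed, params, noise, window)
    })
  })
}

#' Summarize a sweep or cohort table per condition
#'
#' Mean and SD of the windowed trial force per (`kappa`, `condition`) cell.
#'
#' @param table A TrialTable tibble (from [kappa_sweep()] or
#'   [simulate_cohort()]).
#' @return A tibble with one row per (`kappa`, `condition`).
#' @export
summarize_sweep <- function(table) {
  table |>
    dplyr::group_by(.data$kappa, .data$condition) |>
    dplyr::summarise(sd_force_N = sd(.data$mean_force_N),
                     mean_force_N = mean(.data$mean_force_N),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::select("kappa", "condition", "mean_force_N", "sd_force_N",
                  "n_trials") |>
    dplyr::arrange(.data$kappa, .data$condition)
}

#' Write a TrialTable with a JSON config sidecar
#'
#' @param table A TrialTable tibble.
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.config.json`.
#' @param config A list recorded verbatim in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path, config = list()) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  jsonlite::write_json(config, paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
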