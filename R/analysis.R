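#' Remove per-block force offsets
#'
#' Posture shifts between blocks bias the raw force readings; the pipeline
#' subtracts the grand mean force of each block (all samples, all its trials)
#' from every sample of that block, so corrected data have exactly zero mean
#' per block. Grouping is by `block`, and additionally by `pid` when that
#' column is present.
#'
#' @param traces A data frame with a `force` column and a `block` column
#'   (optionally `pid`); any other columns pass through.
#' @return The same frame with `force` replaced by its block-centred value.
#' @export
remove_block_offset <- function(traces) {
  if (!all(c("force", "block") %in% names(traces)))
    stop("`traces` needs columns `force` and `block`", call. = FALSE)
  if (nrow(traces) == 0) stop("no samples: empty block(s)", call. = FALSE)
  keys <- intersect(c("pid", "block"), names(traces))
  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(force = .data$force - mean(.data$force)) |>
    dplyr::ungroup()
}

#' Windowed mean force of a trial
#'
#' Arithmetic mean of the force samples in the half-open analysis window
#' `[t0, t1)` — by default 10-15 s of the stimulation phase, i.e. 5000
#' samples at 1 kHz.
#'
#' @param trial A `vhi_trial` tibble, or any data frame with `time` and
#'   `force` columns.
#' @param t0,t1 Window bounds, s.
#' @return The mean force (N) over the window.
#' @export
window_mean <- function(trial, t0 = 10, t1 = 15) {
  if (t1 <= t0) stop("empty window: need t0 < t1", call. = FALSE)
  step <- if (nrow(trial) > 1) trial$time[2] - trial$time[1] else 0
  if (t0 < min(trial$time) - 1e-9 || t1 > max(trial$time) + step + 1e-9)
    stop("window [", t0, ", ", t1, ") not covered by the trace", call. = FALSE)
  sel <- trial$time >= t0 & trial$time < t1
  if (!any(sel)) stop("no samples in window", call. = FALSE)
  mean(trial$force[sel])
}

check_trial_table <- function(table) {
  need <- c("pid", "group", "condition", "mean_force_N")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("trial table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(table)
}

#' Two-way ANOVA of trial forces: virtual-hand location by stimulation mode
#'
#' Tests the windowed per-trial force against virtual-hand location (3
#' levels, within participants) and visuo-tactile stimulation mode
#' (synchronous vs asynchronous, between participants), with interaction.
#' At trial level on the full 14-participant design (1680 trials) the
#' residual df is 1674 (`N - 6` cell means), matching the human analysis; a
#' participant-level aggregation is available via `unit = "participant"`.
#'
#' @param table A TrialTable with `pid`, `group`, `condition`,
#'   `mean_force_N`.
#' @param unit `"trial"` (default) or `"participant"` (aggregate per
#'   participant and condition before fitting).
#' @return An object of class `vhi_anova`; see [tidy.vhi_anova()].
#' @export
anova_location_mode <- function(table, unit = c("trial", "participant")) {
  unit <- match.arg(unit)
  check_trial_table(table)
  cells <- table |>
    dplyr::count(.data$condition, .data$group)
  full <- tidyr::expand_grid(condition = c("Left", "Center", "Right"),
                             group = unique(table$group))
  miss <- dplyr::anti_join(full, cells, by = c("condition", "group"))
  low <- cells[cells$n < 2, ]
  if (nrow(miss) || nrow(low)) {
    bad <- rbind(miss[c("condition", "group")], low[c("condition", "group")])
    stop("missing or underfilled cell(s): ",
         paste(bad$condition, bad$group, sep = "/", collapse = "; "),
         call. = FALSE)
  }
  df <- if (unit == "participant") {
    table |>
      dplyr::group_by(.data$pid, .data$group, .data$condition) |>
      dplyr::summarise(mean_force_N = mean(.data$mean_force_N),
                       .groups = "drop")
  } else table
  df$condition <- factor(df$condition, levels = c("Left", "Center", "Right"))
  df$group <- factor(df$group)
  fit <- stats::lm(mean_force_N ~ condition * group, data = df)
  at <- stats::anova(fit)
  terms <- rownames(at)
  res <- tibble::tibble(
    term = c("location", "mode", "location:mode")[match(
      c("condition", "group", "condition:group"), terms)],
    df1 = at$Df[match(c("condition", "group", "condition:group"), terms)],
    df2 = at$Df[terms == "Residuals"],
    statistic = at$`F value`[match(c("condition", "group", "condition:group"),
                                   terms)],
    p.value = at$`Pr(>F)`[match(c("condition", "group", "condition:group"),
                                terms)]
  )
  structure(list(table = res, fit = fit, unit = unit, n = nrow(df)),
            class = "vhi_anova")
}

#' @export
print.vhi_anova <- function(x, ...) {
  cat(sprintf("<vhi_anova> %s-level, n = %d, residual df = %d\n",
              x$unit, x$n, x$table$df2[1]))
  print(x$table)
  invisible(x)
}

#' Tidy an ANOVA of trial forces
#'
#' @param x A `vhi_anova` object.
#' @param ... Unused.
#' @return A tibble with `term`, `df1`, `df2`, `statistic`, `p.value`.
#' @export
tidy.vhi_anova <- function(x, ...) x$table

#' @export
glance.vhi_anova <- function(x, ...) {
  tibble::tibble(n = x$n, df_residual = x$table$df2[1], unit = x$unit,
                 r.squared = summary(x$fit)$r.squared)
}

# One-sample / paired t statistics with the zero-variance limit handled as
# strict acceptance (t = 0, p at its null value) or rejection (|t| = Inf,
# p = 0 when the deviation matches the alternative, 1 otherwise).
safe_t <- function(x, alternative = "two.sided") {
  n <- length(x)
  if (sd(x) < 1e-300) {
    m <- mean(x)
    if (abs(m) < 1e-300)
      return(list(t = 0, df = n - 1,
                  p = if (alternative == "two.sided") 1 else 0.5))
    t <- Inf * sign(m)
    p <- switch(alternative,
                two.sided = 0,
                greater = if (m > 0) 0 else 1,
                less = if (m < 0) 0 else 1)
    return(list(t = t, df = n - 1, p = p))
  }
  tt <- stats::t.test(x, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Per-participant post-hoc t-tests of the condition forces
#'
#' Aggregates the trial forces per participant and condition, then runs the
#' directional hypothesis tests of the force analysis: a one-sample t-test of
#' the Center condition against zero (two-tailed, with the one-tailed upper
#' p also reported), a paired one-tailed test of Right vs Center
#' (alternative: Right larger) and of Left vs Center (alternative: Left
#' smaller).
#'
#' @param table A TrialTable with `pid`, `group`, `condition`,
#'   `mean_force_N`; every participant must have all three conditions.
#' @return An object of class `vhi_posthoc`; `tidy()` gives one row per test
#'   with `estimate` (mean, N), `statistic`, `df`, `p.value`, `alternative`.
#' @export
posthoc_tests <- function(table) {
  check_trial_table(table)
  agg <- table |>
    dplyr::group_by(.data$pid, .data$condition) |>
    dplyr::summarise(m = mean(.data$mean_force_N), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "m")
  for (cond in c("Left", "Center", "Right"))
    if (!cond %in% names(agg) || anyNA(agg[[cond]]))
      stop("participant(s) missing condition ", cond, call. = FALSE)
  if (nrow(agg) < 2) stop("need at least 2 participants", call. = FALSE)
  center <- safe_t(agg$Center, "two.sided")
  center1 <- safe_t(agg$Center, "greater")
  right <- safe_t(agg$Right - agg$Center, "greater")
  left <- safe_t(agg$Left - agg$Center, "less")
  res <- tibble::tibble(
    test = c("center_vs_zero", "center_vs_zero_upper",
             "right_vs_center", "left_vs_center"),
    estimate = c(mean(agg$Center), mean(agg$Center),
                 mean(agg$Right - agg$Center), mean(agg$Left - agg$Center)),
    statistic = c(center$t, center1$t, right$t, left$t),
    df = c(center$df, center1$df, right$df, left$df),
    p.value = c(center$p, center1$p, right$p, left$p),
    alternative = c("two.sided", "greater", "greater", "less")
  )
  structure(list(table = res, n_participants = nrow(agg),
                 condition_means = colMeans(agg[c("Left", "Center", "Right")])),
            class = "vhi_posthoc")
}

#' @export
print.vhi_posthoc <- function(x, ...) {
  cat(sprintf("<vhi_posthoc> %d participants\n", x$n_participants))
  print(x$table)
  invisible(x)
}

#' @rdname posthoc_tests
#' @param x A `vhi_posthoc` object.
#' @param ... Unused.
#' @export
tidy.vhi_posthoc <- function(x, ...) x$table

#' @export
glance.vhi_posthoc <- function(x, ...) {
  tibble::tibble(n_participants = x$n_participants,
                 mean_left = x$condition_means[["Left"]],
                 mean_center = x$condition_means[["Center"]],
                 mean_right = x$condition_means[["Right"]])
}

#' Run the full force-statistics pipeline on a trial table
#'
#' Convenience wrapper: condition summaries, the location-by-mode ANOVA and
#' the per-participant post-hoc tests in one object.
#'
#' @param table A TrialTable.
#' @return An object of class `vhi_stats` with elements `summary` (tibble),
#'   `anova` (`vhi_anova`) and `posthoc` (`vhi_posthoc`).
#' @export
analyze_forces <- function(table) {
  check_trial_table(table)
  summary <- table |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(sd_force_N = sd(.data$mean_force_N),
                     mean_force_N = mean(.data$mean_force_N),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::select("condition", "mean_force_N", "sd_force_N", "n_trials")
  structure(list(summary = summary,
                 anova = anova_location_mode(table),
                 posthoc = posthoc_tests(table)),
            class = "vhi_stats")
}

#' @export
print.vhi_stats <- function(x, ...) {
  cat("<vhi_stats>\nPer-condition windowed mean force:\n")
  print(x$summary)
  print(x$anova)
  print(x$posthoc)
  invisible(x)
}

#' @export
tidy.vhi_stats <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$anova$table, test = paste0("anova_", .data$term),
                  .before = 1) |> dplyr::select(-"term"),
    dplyr::rename(x$posthoc$table, df1 = "df") |>
      dplyr::select(-"alternative", -"estimate")
  )
}

#' @export
glance.vhi_stats <- function(x, ...) {
  cbind(glance(x$anova)[c("n", "df_residual")], glance(x$posthoc))
}

#' Synthesize a human-scale force trial table
#'
#' Generates a synthetic stand-in for the human force data with the full
#' experimental structure from [generate_schedule()]: per-condition mean
#' shifts, participant-level random intercepts, participant-by-condition
#' deviations, and trial-level noise. The defaults encode the scale of the
#' reported human statistics (lateral effects of about -0.039 / +0.036 N and
#' variance components consistent with the published test statistics); this
#' is simulated data, not the recorded measurements.
#'
#' @param effects Named numeric: mean force per condition, N.
#' @param n_participants Number of participants (14 reproduces the 1680-trial
#'   design).
#' @param sd_trial Trial-level noise SD, N.
#' @param sd_participant Participant random-intercept SD, N.
#' @param sd_slope Participant-by-condition deviation SD, N.
#' @param seed Integer seed.
#' @return A TrialTable tibble with `pid`, `group`, `block`, `trial`
#'   (position in block), `condition`, `mean_force_N`.
#' @examples
#' nrow(synth_force_table(n_participants = 14, seed = 1))
#' @export
synth_force_table <- function(effects = c(Left = -0.039, Center = 0,
                                          Right = 0.036),
                              n_participants = 14,
                              sd_trial = 0.22, sd_participant = 0.03,
                              sd_slope = 0.04, seed = 1) {
  stopifnot(all(c("Left", "Center", "Right") %in% names(effects)),
            sd_trial >= 0, sd_participant >= 0, sd_slope >= 0)
  sched <- generate_schedule(n_participants, seed = derive_seed(seed, "sched"))
  if (nrow(sched) == 0) return(tibble::tibble(
    pid = integer(), group = character(), block = integer(),
    trial = integer(), condition = character(), mean_force_N = numeric()))
  set.seed(derive_seed(seed, "forces"))
  intercept <- rnorm(n_participants, 0, sd_participant)
  slope <- matrix(rnorm(n_participants * 3, 0, sd_slope), n_participants, 3,
                  dimnames = list(NULL, c("Left", "Center", "Right")))
  sched |>
    dplyr::mutate(
      trial = .data$position,
      mean_force_N = as.numeric(effects[.data$condition]) +
        intercept[.data$pid] +
        slope[cbind(.data$pid, match(.data$condition, colnames(slope)))] +
        rnorm(dplyr::n(), 0, sd_trial)
    ) |>
    dplyr::select("pid", "group", "block", "trial", "condition",
                  "mean_force_N")
}

#' Read a trial table from CSV
#'
#' Accepts the package's TrialTable schema, with an optional column mapping
#' for externally produced files.
#'
#' @param path CSV path.
#' @param col_map Optional named character vector mapping the required names
#'   (`pid`, `group`, `condition`, `mean_force_N`, optionally `block`,
#'   `trial`) to the columns present in the file.
#' @return A TrialTable tibble.
#' @export
read_trial_table <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map))
    for (nm in names(col_map)) names(df)[names(df) == col_map[[nm]]] <- nm
  check_trial_table(df)
  tibble::as_tibble(df)
}
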