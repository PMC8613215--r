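vhi_cond_scale <- function() {
  ggplot2::scale_colour_manual(
    values = c(Left = "#3b6fb6", Center = "#3aa655", Right = "#c84b4b"),
    aesthetics = c("colour", "fill"))
}

#' Plot a simulated trial
#'
#' Lateral force, inferred elbow angle and perceived virtual-hand position
#' against time, as stacked facets.
#'
#' @param object A `vhi_trial` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vhi_trial <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("force", "mu0", "nu_cm"), names_to = "channel") |>
    dplyr::mutate(channel = factor(.data$channel, c("force", "mu0", "nu_cm"),
                                   c("lateral force (N)",
                                     "inferred elbow angle (rad)",
                                     "perceived virtual hand (cm)")))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(colour = "#2c3e50") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("Trial at offset %+g cm",
                                  attr(object, "offset_cm"))) +
    ggplot2::theme_minimal()
}

#' Plot a visuo-tactile event train
#'
#' Visual (ball-contact) and tactile (vibration) event times with the
#' per-pair delay.
#'
#' @param object A `vhi_events` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vhi_events <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(delay = .data$tactile_time_s - .data$visual_time_s)
  ggplot2::ggplot(df, ggplot2::aes(.data$visual_time_s, .data$delay)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$visual_time_s, yend = 0),
                          colour = "grey55") +
    ggplot2::geom_point(colour = "#2c3e50") +
    ggplot2::geom_hline(yintercept = 0.1, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "visual event time (s)",
                  y = "tactile delay (s)",
                  title = sprintf("%s stimulation", unique(df$mode))) +
    ggplot2::theme_minimal()
}

#' Mean force per condition, with spread
#'
#' Condition-wise mean and SD of the windowed trial force, optionally split
#' by stimulation group — the standard summary panel for a cohort or human
#' trial table.
#'
#' @param table A TrialTable tibble.
#' @param by_group Facet by `group`?
#' @return A ggplot object.
#' @export
plot_force_summary <- function(table, by_group = FALSE) {
  keys <- if (by_group) c("group", "condition") else "condition"
  df <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(m = mean(.data$mean_force_N),
                     s = sd(.data$mean_force_N), .groups = "drop") |>
    dplyr::mutate(condition = factor(.data$condition,
                                     c("Left", "Center", "Right")))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$m,
                                        colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$m - .data$s,
                                          ymax = .data$m + .data$s)) +
    vhi_cond_scale() +
    ggplot2::labs(x = NULL, y = "mean lateral force (N)", colour = NULL) +
    ggplot2::theme_minimal()
  if (by_group) p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$group))
  p
}

#' Plot a causality-parameter sweep
#'
#' Mean and SD of the windowed force per condition as a function of the
#' causality weight kappa.
#'
#' @param sweep_table A TrialTable from [kappa_sweep()] (or its
#'   [summarize_sweep()] output).
#' @return A ggplot object.
#' @export
plot_kappa_sweep <- function(sweep_table) {
  df <- if ("sd_force_N" %in% names(sweep_table)) sweep_table
        else summarize_sweep(sweep_table)
  df$condition <- factor(df$condition, c("Left", "Center", "Right"))
  ggplot2::ggplot(df, ggplot2::aes(.data$kappa, .data$mean_force_N,
                                   colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_force_N - .data$sd_force_N,
      ymax = .data$mean_force_N + .data$sd_force_N),
      position = ggplot2::position_dodge(width = 0.03)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.03)) +
    vhi_cond_scale() +
    ggplot2::labs(x = expression(kappa), y = "mean lateral force (N)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
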