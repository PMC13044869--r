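# ggplot2 views of the main result types.

#' Plot event-aligned epochs
#'
#' Mean +/- SEM trace across trials, optionally split by role.
#'
#' @param object An `epoch_set`.
#' @param by_role Facet the ribbon by role (default `TRUE` when more than
#'   one role is present).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.epoch_set <- function(object, by_role = NULL, ...) {
  df <- tibble::as_tibble(object)
  by_role <- by_role %||% (length(unique(df$role)) > 1L)
  grp <- if (by_role) c("role", "t_rel_s") else "t_rel_s"
  agg <- dplyr::summarise(
    dplyr::group_by(df, dplyr::across(dplyr::all_of(grp))),
    mean_z = mean(z), sem_z = stats::sd(z) / sqrt(dplyr::n()), .groups = "drop"
  )
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = t_rel_s, y = mean_z)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean_z - sem_z, ymax = mean_z + sem_z),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from onset (s)", y = "z-scored ΔF/F") +
    ggplot2::theme_minimal()
  if (by_role) p <- p + ggplot2::facet_wrap(~role)
  p
}

#' Plot the per-subject contrasts of an experiment
#'
#' Paired dots (one line per subject) of the mean peak-to-trough
#' amplitude for the deviant, standard and many-standards
#' deviant-equivalent conditions.
#'
#' @param object A `da_experiment` from [run_oddball_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.da_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(object$contrasts, -subject,
                              names_to = "condition", values_to = "peak_to_trough_z")
  long$condition <- factor(long$condition, levels = c("dev", "std", "ms"),
                           labels = c("Dev", "Std", "MS"))
  ggplot2::ggplot(long, ggplot2::aes(condition, peak_to_trough_z, group = subject)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean, geom = "crossbar",
                          width = 0.4, linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "peak-to-trough (z)") +
    ggplot2::theme_minimal()
}

#' Plot an occupancy heatmap
#'
#' Displays the binned occupancy grid; with `pseudo_log = TRUE` the fill
#' uses a pseudo-logarithmic transform (`asinh(pct / (2 sigma))` style,
#' base 10), which is a display choice only and does not alter the
#' metric.
#'
#' @param grid Output of [occupancy_heatmap()].
#' @param pseudo_log Use a pseudo-log color scale (default `TRUE`).
#' @param sigma Linearization scale of the pseudo-log transform.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(grid, pseudo_log = TRUE, sigma = 0.001) {
  p <- ggplot2::ggplot(grid, ggplot2::aes(x_cm, y_cm, fill = pct)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", fill = "% time") +
    ggplot2::theme_minimal()
  if (pseudo_log) {
    p <- p + ggplot2::scale_fill_viridis_c(
      trans = scales::pseudo_log_trans(sigma = sigma, base = 10),
      na.value = "grey90")
  } else {
    p <- p + ggplot2::scale_fill_viridis_c()
  }
  p
}

#' Plot the dopamine response kernel
#'
#' Renders the noise-free stimulus-locked response for a single event.
#'
#' @param kernel A [kernel_params()].
#' @param duration_s Stimulus duration (s).
#' @param sensor A [sensor_params()].
#' @param sampling_rate_hz Evaluation grid rate.
#' @return A ggplot object.
#' @export
plot_kernel <- function(kernel = kernel_params(), duration_s = 6,
                        sensor = sensor_params(), sampling_rate_hz = 1000) {
  ev <- stim_simple(duration_s = duration_s, n_events = 1)
  tr <- dopamine_kernel(ev, kernel, sensor, sampling_rate_hz = sampling_rate_hz)
  ggplot2::ggplot(tr, ggplot2::aes(time_s, response)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = 0, xmax = duration_s, ymin = -Inf, ymax = Inf,
                      alpha = 0.08) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = "response (z)") +
    ggplot2::theme_minimal()
}
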