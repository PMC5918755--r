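#' Plot a simulated trust trajectory
#'
#' Shows each group's mean willingness to collaborate with the other group
#' against time on a logarithmic axis, with thin per-replication lines and
#' a heavy aggregate line per group. `autoplot()` on a `trust_sim` object
#' is equivalent.
#'
#' @param trajectory A trajectory tibble (with or without a `replication`
#'   column), as returned by [tidy()] on a simulation.
#' @param t_enlightenment Optional enlightenment time to mark with a
#'   vertical dashed line.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory, t_enlightenment = NULL) {
  long <- function(df) {
    tidyr::pivot_longer(
      df,
      cols = c("mean_dominant_to_subordinate", "mean_subordinate_to_dominant"),
      names_to = "direction", values_to = "willingness")
  }
  shown <- dplyr::filter(trajectory, .data$time >= 1)
  p <- ggplot2::ggplot(long(shown),
                       ggplot2::aes(x = .data$time, y = .data$willingness,
                                    colour = .data$direction))
  if ("replication" %in% names(trajectory) &&
      length(unique(trajectory$replication)) > 1) {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(group = interaction(
        .data$replication, .data$direction)), alpha = 0.25, linewidth = 0.3) +
      ggplot2::geom_line(data = long(aggregate_replications(shown)),
                         linewidth = 1)
  } else {
    p <- p + ggplot2::geom_line(linewidth = 0.8)
  }
  if (!is.null(t_enlightenment) && t_enlightenment > 0) {
    p <- p + ggplot2::geom_vline(xintercept = t_enlightenment,
                                 linetype = "dashed", colour = "grey40")
  }
  p +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(mean_dominant_to_subordinate = "#B2182B",
                 mean_subordinate_to_dominant = "#2166AC"),
      labels = c(mean_dominant_to_subordinate = "dominant → subordinate",
                 mean_subordinate_to_dominant = "subordinate → dominant"),
      name = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (interactions, log scale)",
                  y = "mean willingness to collaborate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' @rdname plot_trajectory
#' @param object A `trust_sim` object.
#' @param ... Unused.
#' @method autoplot trust_sim
#' @export
autoplot.trust_sim <- function(object, ...) {
  t_e <- if (object$config$intervention_mode == "instant_enlightenment") {
    object$config$t_enlightenment
  } else NULL
  plot_trajectory(object$trajectories, t_enlightenment = t_e)
}

#' Plot the evolution of group-mean learning rates
#'
#' Under conformity the learning rate of each agent is its distance from
#' the group norm; as groups consolidate around their norms the mean
#' learning rate decays, which is the mechanism that locks stigma in.
#'
#' @param trajectory A trajectory tibble.
#' @return A ggplot object.
#' @export
plot_learning_rates <- function(trajectory) {
  shown <- dplyr::filter(trajectory, .data$time >= 1)
  if ("replication" %in% names(shown)) {
    shown <- aggregate_replications(shown)
  }
  long <- tidyr::pivot_longer(
    shown, cols = c("mean_alpha_dominant", "mean_alpha_subordinate"),
    names_to = "group", values_to = "alpha")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$alpha,
                                     colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(mean_alpha_dominant = "#B2182B",
                 mean_alpha_subordinate = "#2166AC"),
      labels = c(mean_alpha_dominant = "dominant group",
                 mean_alpha_subordinate = "subordinate group"),
      name = NULL) +
    ggplot2::labs(x = "time (interactions, log scale)",
                  y = "mean learning rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
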