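# ggplot2 views of the main result objects.

#' Plot a phase sweep
#'
#' Three panels versus the ratio n = N/M: the ensemble-averaged per-species H,
#' the frozen fraction phi, and the relative number of bidirectional reactions
#' n (1 - phi) with the marginal line at 1. Curves are coloured by initial
#' condition; in the balanced phase (H near 0) the two curves separate — the
#' signature of broken ergodicity.
#'
#' @param object A `phase_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_sweep <- function(object, ...) {
  df <- as_tibble(object)
  long <- dplyr::bind_rows(
    tibble(n = df$n, init = df$init, panel = "H per species",
           value = df$H_mean, se = df$H_se),
    tibble(n = df$n, init = df$init, panel = "phi (frozen fraction)",
           value = df$phi, se = df$phi_se),
    tibble(n = df$n, init = df$init, panel = "n (1 - phi)",
           value = df$nbid, se = df$nbid_se))
  ref <- tibble(panel = "n (1 - phi)", yint = 1)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value,
                                     colour = .data$init)) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$yint),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - 2 * .data$se,
                                          ymax = .data$value + 2 * .data$se),
                             size = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "n = N / M", y = NULL, colour = "initial condition") +
    ggplot2::theme_minimal()
}

#' Plot a trajectory record
#'
#' Accumulator trajectories on a log time axis (bounded accumulators =
#' bidirectional reactions, linear drift = frozen ones) with the running H
#' overlaid in a second panel.
#'
#' @param object A `trajectory_record`.
#' @param max_reactions At most this many accumulator traces are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_record <- function(object, max_reactions = 30, ...) {
  df <- tidy(object)
  keep <- unique(df$reaction)
  if (length(keep) > max_reactions) keep <- keep[seq_len(max_reactions)]
  h <- tibble(step = object$checkpoint_steps, H = object$H_series)
  p1 <- ggplot2::ggplot(df[df$reaction %in% keep, ],
                        ggplot2::aes(.data$step, .data$y,
                                     group = .data$reaction)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "step", y = "accumulator y") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(h, ggplot2::aes(.data$step, .data$H)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "step", y = "H of running flux") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(p1, p2, ncol = 1, heights = c(2, 1))
  } else {
    p1
  }
}
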