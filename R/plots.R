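#' Positional RBP map (motif score or peak density profile)
#'
#' Draws the per-position mean motif score (or binding-site density) across
#' the eight segments, one panel per segment, coloured by event group —
#' the layout of the classic cassette-exon RNA maps.
#'
#' @param object a `motif_profile` or `peak_profile`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot motif_profile
#' @export
autoplot.motif_profile <- function(object, ...) {
  df <- object$profile |>
    mutate(segment = factor(.data$segment, levels = segment_names))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score,
                                   colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(. ~ segment, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position in segment (nt, transcript orientation)",
                  y = "motif score (% covered in window)",
                  colour = "events") +
    ggplot2::theme_minimal(base_size = 9)
}

#' @rdname autoplot.motif_profile
#' @method autoplot peak_profile
#' @export
autoplot.peak_profile <- function(object, ...) {
  df <- object$profile |>
    mutate(segment = factor(.data$segment, levels = segment_names))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$density,
                                   colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(. ~ segment, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position in segment (nt)",
                  y = "fraction of events with a binding site",
                  colour = "events") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Volcano-style differential usage plot
#'
#' @param object an `isodyn_dtu` result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot isodyn_dtu
#' @export
autoplot.isodyn_dtu <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dIF,
                                       y = -log10(pmax(.data$padj, 1e-300)),
                                       colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-0.1, 0.1), linetype = 2,
                        linewidth = 0.3) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "dIF (isoform fraction change)",
                  y = expression(-log[10] ~ "FDR")) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Inclusion-level change plot for cassette exons
#'
#' @param object an `isodyn_psi` result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot isodyn_psi
#' @export
autoplot.isodyn_psi <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dPsi,
                                       y = -log10(pmax(.data$FDR, 1e-300)),
                                       colour = .data$regulation)) +
    ggplot2::geom_point(size = 0.9, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-0.05, 0.05), linetype = 2,
                        linewidth = 0.3) +
    ggplot2::labs(x = expression(Delta * Psi), y = expression(-log[10] ~ "FDR")) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Event gain/loss bar chart
#'
#' @param summary a [gain_loss_summary()] table.
#' @return a ggplot object.
#' @export
plot_gain_loss <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$event_type, y = .data$fraction,
                               fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "event type", y = "fraction of gained/lost events") +
    ggplot2::theme_minimal(base_size = 9)
}
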