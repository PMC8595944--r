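#' Plot a normalized spectrum
#'
#' One line per channel on a log10 power scale.
#'
#' @param object An [eeg_spectrum()].
#' @param max_freq Upper frequency limit of the panel (default 30 Hz).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eeg_spectrum
#' @export
autoplot.eeg_spectrum <- function(object, max_freq = 30, ...) {
  d <- tidy(object) %>% dplyr::filter(.data$frequency <= max_freq)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$psdn,
                                  colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Normalized PSD (unit sum)",
                  title = sprintf("Subject %s", object$subject_id)) +
    ggplot2::theme_minimal()
}

#' Plot group-median spectra with quartile ribbons
#'
#' @param curves Output of [group_median_spectrum()].
#' @param max_freq Upper frequency limit (default 4 Hz, the delta range
#'   where the slow-oscillation peak lives).
#' @return A ggplot object.
#' @export
plot_group_spectra <- function(curves, max_freq = 4) {
  d <- curves %>% dplyr::filter(.data$frequency <= max_freq)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, colour = .data$group,
                                  fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 0.6) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Normalized PSD (unit sum)") +
    ggplot2::theme_minimal()
}

#' Plot a correlation network
#'
#' Fruchterman--Reingold embedding with edge width proportional to the
#' absolute correlation and color by sign (red negative, green positive);
#' node color by module when the partition has been computed.
#'
#' @param object An annotated `cor_network` (see [annotate_network()]).
#' @param label_non_eeg Label PSG/cognitive nodes (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cor_network
#' @export
autoplot.cor_network <- function(object, label_non_eeg = TRUE, ...) {
  if (is.null(object$layout)) {
    object <- layout_fruchterman_reingold(object)
  }
  nodes <- network_nodes(object)
  edges <- tidy(object)
  if (nrow(edges) > 0) {
    edges <- edges %>%
      dplyr::left_join(nodes %>% dplyr::select("node", "x", "y"),
                       by = c(from = "node")) %>%
      dplyr::rename(x_from = "x", y_from = "y") %>%
      dplyr::left_join(nodes %>% dplyr::select("node", "x", "y"),
                       by = c(to = "node")) %>%
      dplyr::rename(x_to = "x", y_to = "y")
  }
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x_from, y = .data$y_from, xend = .data$x_to,
                   yend = .data$y_to, linewidth = .data$abs_weight,
                   colour = .data$sign),
      alpha = 0.6) +
      ggplot2::scale_colour_manual(values = c(positive = "#2e7d32",
                                              negative = "#c62828")) +
      ggplot2::scale_linewidth_continuous(range = c(0.1, 1.5))
  }
  aes_nodes <- if ("module" %in% names(nodes)) {
    ggplot2::aes(x = .data$x, y = .data$y, fill = factor(.data$module),
                 shape = .data$type)
  } else {
    ggplot2::aes(x = .data$x, y = .data$y, shape = .data$type)
  }
  p <- p + ggplot2::geom_point(data = nodes, aes_nodes, size = 2, stroke = 0.2) +
    ggplot2::scale_shape_manual(values = c(eeg = 21, psg = 22, cognitive = 24,
                                           other = 23))
  if (label_non_eeg && any(nodes$type != "eeg")) {
    p <- p + ggplot2::geom_text(
      data = nodes %>% dplyr::filter(.data$type != "eeg"),
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      size = 2.5, vjust = -1)
  }
  p + ggplot2::theme_void() +
    ggplot2::labs(fill = "Module", shape = "Node type", colour = "Sign",
                  linewidth = "|rho|")
}

#' Radar chart of band-averaged absolute correlations
#'
#' @param summary Output of [radar_summary()], possibly row-bound over
#'   several groups with a `group` column added.
#' @param panel Which panel to draw (default `"eeg_vs_psg"`).
#' @return A ggplot object (polar coordinates).
#' @export
plot_radar <- function(summary, panel = "eeg_vs_psg") {
  d <- summary %>% dplyr::filter(.data$panel == !!panel) %>%
    dplyr::group_by(dplyr::across(dplyr::any_of(c("group", "axis")))) %>%
    dplyr::summarise(mean_abs_rho = mean(.data$mean_abs_rho), .groups = "drop")
  aes <- if ("group" %in% names(d)) {
    ggplot2::aes(x = .data$axis, y = .data$mean_abs_rho,
                 colour = .data$group, group = .data$group)
  } else {
    ggplot2::aes(x = .data$axis, y = .data$mean_abs_rho, group = 1)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "Mean |rho|", title = panel) +
    ggplot2::theme_minimal()
}
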