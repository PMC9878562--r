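# Presentation-only figures (excluded from any bit-exactness guarantee).

#' Gated scatter of directionality vs arrest coefficient
#'
#' @param assignment A `gate_assignment` from [gate_counts()].
#' @return A ggplot object, faceted by group.
#' @export
plot_gate_scatter <- function(assignment) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_config("plot_gate_scatter needs the ggplot2 package")
  }
  df <- gate_scatter_export(assignment)
  cfg <- assignment$config
  ggplot2::ggplot(df, ggplot2::aes(x = .data$A, y = .data$Gamma,
                                   color = .data$gate)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = cfg$a_star, linetype = 2) +
    ggplot2::geom_hline(yintercept = cfg$d_star, linetype = 2) +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_color_manual(values = c(chemokinesis = "#2ca02c",
                                           immobile = "#1f77b4",
                                           polarized = "#d62728",
                                           directional = "#ff7f0e")) +
    ggplot2::labs(x = "arrest coefficient", y = "directionality") +
    ggplot2::theme_minimal()
}

#' Common-origin track plot
#'
#' @param table A `track_table`.
#' @return A ggplot object (x-y projection), faceted by group.
#' @export
plot_common_origin <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_config("plot_common_origin needs the ggplot2 package")
  }
  df <- as_tibble(common_origin(table))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$cell_id)) +
    ggplot2::geom_path(alpha = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(~group) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
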