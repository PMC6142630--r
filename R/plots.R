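#' Plot a tSNE embedding colored by a label
#'
#' @param embedding An [embed_tsne()] result.
#' @param labels Optional tibble with `cell_id` and a label column.
#' @param colour Name of the label column (default the first non-id column).
#' @return A ggplot.
#' @export
plot_embedding <- function(embedding, labels = NULL, colour = NULL) {
  df <- embedding
  if (!is.null(labels)) {
    df <- dplyr::left_join(df, labels, by = "cell_id")
    if (is.null(colour)) colour <- setdiff(names(labels), "cell_id")[1]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$tsne1, .data$tsne2)) +
    ggplot2::labs(x = "tSNE 1", y = "tSNE 2")
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 1.5)
  } else {
    p <- p + ggplot2::geom_point(size = 1.5)
  }
  p + ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.hox_embed <- function(object, ...) plot_embedding(object, ...)

#' Plot a diffusion map with optional group centroids
#'
#' Cells in the (DC1, DC2) plane, optionally colored by combination label
#' or pseudo-time, with group centroids overlaid.
#'
#' @param dr A [diffusion_map()] result.
#' @param calls Optional [call_combinations()] output for coloring.
#' @param pt Optional [dpt()] output; colors by pseudo-time instead.
#' @param centroids Optional centroid tibble from
#'   [group_centroids_and_progression()].
#' @return A ggplot.
#' @export
plot_diffusion <- function(dr, calls = NULL, pt = NULL, centroids = NULL) {
  df <- tibble::tibble(cell_id = dr$cell_ids,
                       DC1 = dr$components[, 1], DC2 = dr$components[, 2])
  if (!is.null(pt)) {
    df <- dplyr::left_join(df, pt, by = "cell_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$DC1, .data$DC2,
                                          colour = .data$pseudotime)) +
      ggplot2::geom_point(size = 1.5) +
      ggplot2::scale_colour_viridis_c()
  } else if (!is.null(calls)) {
    lab <- combination_labels(calls)
    df <- dplyr::left_join(df, lab, by = "cell_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$DC1, .data$DC2,
                                          colour = .data$label)) +
      ggplot2::geom_point(size = 1.5)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$DC1, .data$DC2)) +
      ggplot2::geom_point(size = 1.5)
  }
  if (!is.null(centroids)) {
    p <- p + ggplot2::geom_point(data = centroids, size = 4, shape = 4,
                                 ggplot2::aes(colour = NULL))
  }
  p + ggplot2::theme_minimal()
}

#' Stacked per-cell cumulative panel expression
#'
#' Cells ordered by total panel output, one stacked bar per cell, mirroring
#' cumulative combinatorial expression displays.
#'
#' @param cumulative Output of [cumulative_panel_expression()].
#' @return A ggplot.
#' @export
plot_cumulative <- function(cumulative) {
  ord <- cumulative |>
    dplyr::distinct(.data$cell_id, .data$panel_total) |>
    dplyr::arrange(dplyr::desc(.data$panel_total))
  df <- dplyr::mutate(cumulative,
                      cell_id = factor(.data$cell_id, levels = ord$cell_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$cell_id, .data$expr,
                                   fill = .data$gene)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cell (ordered by panel total)",
                  y = "normalized expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Density plot of two-channel flow events with quadrant gates
#'
#' @param events Event table.
#' @param gates A [gate_quadrants()] result.
#' @return A ggplot on log10 axes with gate lines.
#' @export
plot_quadrants <- function(events, gates) {
  ch <- gates$channels
  df <- tibble::as_tibble(events)
  ggplot2::ggplot(df, ggplot2::aes(.data[[ch[1]]], .data[[ch[2]]])) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_vline(xintercept = gates$thresholds[[1]],
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = gates$thresholds[[2]],
                        linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::theme_minimal()
}
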