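#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a depth profile
#'
#' Line plot of the chosen per-plane metrics against depth.
#'
#' @param object A [plane_metrics()] result.
#' @param metrics Character vector of profile columns to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.depth_profile <- function(object,
                                   metrics = c("fraction", "signal", "noise"),
                                   ...) {
  long <- object |>
    dplyr::select("depth_um", dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(-"depth_um", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$depth_um, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "depth (µm)", y = NULL,
                  title = "Per-plane staining metrics") +
    ggplot2::theme_minimal()
}

#' Heatmap of normalized staining-quality scores
#'
#' Depth (rows) by condition (columns) tile plot of replicate-averaged
#' scores, one panel per fluorophore group.
#'
#' @param object A [normalize_across_conditions()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.normalized_score <- function(object, ...) {
  avg <- object |>
    dplyr::group_by(.data$fluorophore, .data$condition_id, .data$depth_um) |>
    dplyr::summarise(score = mean(.data$score, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(.data$condition_id, .data$depth_um,
                                    fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "score") +
    ggplot2::facet_wrap(~fluorophore, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "depth (µm)",
                  title = "Normalized staining-quality score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Condition comparison bar chart
#'
#' Mean half-max depth per condition with SEM error bars and significance
#' labels versus baseline, one panel per fluorophore group.
#'
#' @param object A [compare_conditions()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.staining_comparison <- function(object, ...) {
  df <- tidy(object)
  df$label <- ifelse(is.na(df$sig_label) | df$sig_label == "ns", "",
                     df$sig_label)
  ggplot2::ggplot(df, ggplot2::aes(.data$condition_id, .data$mean_um,
                                   fill = .data$baseline)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_um - .data$sem_um,
                   ymax = .data$mean_um + .data$sem_um),
      width = 0.3, na.rm = TRUE
    ) +
    ggplot2::geom_text(
      ggplot2::aes(y = .data$mean_um + 2 * dplyr::coalesce(.data$sem_um, 0),
                   label = .data$label),
      vjust = 0
    ) +
    ggplot2::facet_wrap(~fluorophore, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "half-max depth (µm)",
                  title = "Half-max staining depth vs baseline",
                  fill = "baseline") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
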