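#' Plot per-definition model performance
#'
#' Point-and-CI plot of a metric across the definition grid, grouped by
#' category (follow-up window, size-change metric, TRSC scheme).
#'
#' @param object A `bm_grid_result`.
#' @param metric One of `"auc"`, `"auprc"`, `"sensitivity"`, `"specificity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bm_grid_result <- function(object, metric = "auc", ...) {
  d <- tidy(object) |> dplyr::filter(.data$metric == !!metric)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$experiment,
                                             levels = object$grid$experiment),
                                  y = .data$mean, colour = .data$category)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = "progression definition", y = toupper(metric),
                  colour = "category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of aggregated feature importance across definitions
#'
#' The matrix analogue of a definition-by-feature importance figure: rows are
#' grid experiments, columns features, fill the aggregated \[0, 1\]
#' importance.
#'
#' @param grid_result A `bm_grid_result`.
#' @param top_n Keep only the `top_n` features with the highest importance
#'   variance across experiments (NULL = all 107).
#' @return A ggplot object.
#' @export
plot_importance_heatmap <- function(grid_result, top_n = 30) {
  imp <- grid_result$importance
  long <- tidyr::pivot_longer(imp, -"experiment", names_to = "feature",
                              values_to = "importance")
  if (!is.null(top_n)) {
    keep <- long |>
      dplyr::group_by(.data$feature) |>
      dplyr::summarise(s = mean(.data$importance, na.rm = TRUE)) |>
      dplyr::slice_max(.data$s, n = top_n) |>
      dplyr::pull(.data$feature)
    long <- dplyr::filter(long, .data$feature %in% keep)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature,
                                     y = factor(.data$experiment,
                                                levels = rev(grid_result$grid$experiment)),
                                     fill = .data$importance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "importance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       size = 6))
}

#' Plot simulated lesion volume trajectories
#'
#' Spaghetti plot of the measured volume proxy (diameter product) over time,
#' coloured by true trajectory class.
#'
#' @param object A `bm_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bm_cohort <- function(object, ...) {
  d <- object$measurements |>
    dplyr::mutate(volume = .data$d_pa_mm * .data$d_ml_mm * .data$d_si_mm) |>
    dplyr::left_join(dplyr::select(object$lesions, "lesion_id", "true_class",
                                   "v0_mm3"),
                     by = "lesion_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$months,
                                  y = .data$volume / .data$v0_mm3,
                                  group = .data$lesion_id,
                                  colour = .data$true_class)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "months post-SRS", y = "volume / baseline",
                  colour = "class") +
    ggplot2::theme_minimal()
}
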