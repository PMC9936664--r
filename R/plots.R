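#' Van Krevelen diagram
#'
#' H/C against O/C of the detected formula-bearing peaks, colored by compound
#' class and faceted by group. The tables behind this plot are also written
#' by the pipeline, so fully customized figures can be built from the CSVs.
#'
#' @param x An annotated `ftms_data` object.
#' @param grouping Metadata column.
#' @return A ggplot object.
#' @export
plot_van_krevelen <- function(x, grouping = x$grouping[1]) {
  vk <- van_krevelen_data(x, grouping)
  ggplot2::ggplot(vk, ggplot2::aes(x = .data$OC, y = .data$HC,
                                   color = .data$compound_class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "O/C", y = "H/C", color = "Compound class") +
    ggplot2::theme_bw()
}

#' SPANS-style score heatmap
#'
#' @param grid Output of [spans_grid()].
#' @return A ggplot object (subset methods on y, normalization methods on x,
#'   score as fill; higher/brighter = less group bias).
#' @export
plot_spans_grid <- function(grid) {
  g <- grid
  g$cell <- ifelse(is.na(g$parameter), g$subset_method,
                   paste0(g$subset_method, "_", g$parameter))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$normalization_method, y = .data$cell,
                                  fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "Normalization method", y = "Subset method",
                  fill = "Bias score") +
    ggplot2::theme_minimal()
}
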