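# ggplot2 visualisations: the labelled map as a coloured node grid and the
# evaluation report as confusion heatmaps.

#' Plot a topological map as a coloured node grid
#'
#' Labelled maps are tiled by class (the classic coloured class-territory
#' view); unlabelled maps are shaded by the mean prototype value.
#'
#' @param object A `topo_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.topo_map <- function(object, ...) {
  td <- tidy(object)
  if (!all(is.na(td$label))) {
    p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$col, y = .data$row,
                                          fill = factor(.data$label))) +
      ggplot2::geom_tile(colour = "grey30") +
      ggplot2::scale_fill_brewer(palette = "YlOrBr", name = "class")
  } else {
    td$mean_w <- rowMeans(object$prototypes)
    p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$col, y = .data$row,
                                          fill = .data$mean_w)) +
      ggplot2::geom_tile(colour = "grey30") +
      ggplot2::scale_fill_viridis_c(name = "mean w")
  }
  p + ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row",
                  title = sprintf("%d x %d topological map",
                                  object$grid_shape[1], object$grid_shape[2])) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report as confusion heatmaps
#'
#' One tile panel per partition, rows = true class, columns = predicted.
#'
#' @param object A `compost_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.compost_eval <- function(object, ...) {
  df <- purrr::map_dfr(names(object$partitions), function(p) {
    m <- object$partitions[[p]]$confusion
    d <- as.data.frame(as.table(m))
    names(d) <- c("true", "predicted", "n")
    d$partition <- p
    d
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::facet_wrap(~partition) +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Write the class-territory map view to a PNG file
#'
#' @param model A labelled `topo_map`.
#' @param path Output PNG path.
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
plot_map_png <- function(model, path, width = 5, height = 5, dpi = 150) {
  ggplot2::ggsave(path, autoplot(model), width = width, height = height,
                  dpi = dpi)
  invisible(path)
}
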