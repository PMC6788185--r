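# broom-style tidiers for the fitted objects.

#' Tidy a topological map into one row per node
#'
#' @param x A `topo_map`.
#' @param ... Unused.
#' @return Tibble with `node` (1-based row-major index), 0-based `row` and
#'   `col`, `label`, `support`, and the per-node quantization contribution is
#'   left to [quantization_error()].
#' @export
tidy.topo_map <- function(x, ...) {
  coords <- grid_coords(x$grid_shape)
  tibble::tibble(node = seq_len(nrow(x$prototypes)),
                 row = coords[, 1], col = coords[, 2],
                 label = if (is.null(x$labels)) NA_integer_ else x$labels,
                 support = if (is.null(x$label_support)) NA_integer_
                           else x$label_support)
}

#' One-row summary of a topological map
#'
#' @inheritParams tidy.topo_map
#' @return Tibble with grid dimensions, node and class counts, and — for
#'   LVQ1-tuned maps — the best validation epoch and quality.
#' @export
glance.topo_map <- function(x, ...) {
  lvq <- x$meta$lvq
  tibble::tibble(
    rows = x$grid_shape[1], cols = x$grid_shape[2],
    n_nodes = nrow(x$prototypes), dim = ncol(x$prototypes),
    n_classes = if (is.null(x$labels)) NA_integer_
                else length(unique(x$labels)),
    lvq_best_epoch = if (is.null(lvq)) NA_integer_
                     else as.integer(lvq$best_epoch),
    lvq_best_val_quality = if (is.null(lvq)) NA_real_
                           else max(unlist(lvq$val_quality)))
}

#' Tidy an evaluation report into one row per partition
#'
#' @param x A `compost_eval`.
#' @param ... Unused.
#' @return Tibble with `partition`, `quality`, `rmse`, `n_cases`.
#' @export
tidy.compost_eval <- function(x, ...) {
  purrr::map_dfr(names(x$partitions), function(p)
    tibble::tibble(partition = p,
                   quality = x$partitions[[p]]$quality,
                   rmse = x$partitions[[p]]$rmse,
                   n_cases = x$partitions[[p]]$n_cases))
}

#' One-row summary of an evaluation report
#'
#' @inheritParams tidy.compost_eval
#' @return Tibble with per-partition quality and RMSE in wide form.
#' @export
glance.compost_eval <- function(x, ...) {
  td <- tidy(x)
  wide <- tidyr::pivot_wider(td[, c("partition", "quality", "rmse")],
                             names_from = "partition",
                             values_from = c("quality", "rmse"))
  dplyr::bind_cols(wide, tibble::tibble(n_total = sum(td$n_cases)))
}

#' @export
tidy.compost_run <- function(x, ...) tidy(x$report, ...)

#' @export
glance.compost_run <- function(x, ...) glance(x$report, ...)
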