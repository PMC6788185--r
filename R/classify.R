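# Turning the unsupervised map into a 5-class separator: majority-vote node
# labelling from training winners, total prediction via BMU label, and a
# map-coherence diagnostic over 4-connected class regions.

#' Label map nodes by majority vote of their winning training cases
#'
#' Each node takes the most frequent class among training cases whose BMU it
#' is (ties to the smallest class id). Nodes that win no case inherit the
#' label of the nearest directly-labelled node by Euclidean grid distance
#' (ties to the smallest row-major index), so every input gets a class.
#' `label_support` records the number of winning training cases per node.
#'
#' @param data Tibble with feature columns and `class_id`; rows with
#'   `partition == "train"` are used when a partition column is present.
#' @param map A trained `topo_map`.
#' @return The map with `labels` and `label_support` filled in.
#' @export
label_map <- function(data, map) {
  train <- if (is.data.frame(data)) partition_rows(data, "train") else data
  if (!is.data.frame(train) || !"class_id" %in% names(train) ||
      nrow(train) == 0 || anyNA(train$class_id))
    abort("label_map needs labelled training cases (class_id column)")
  nodes <- nrow(map$prototypes)
  win <- bmu_indices(map, train) + 1L  # 1-based node per case
  labels <- rep(NA_integer_, nodes)
  support <- integer(nodes)
  for (k in unique(win)) {
    cls <- train$class_id[win == k]
    support[k] <- length(cls)
    tab <- table(cls)
    top <- names(tab)[tab == max(tab)]
    labels[k] <- min(as.integer(top))  # tie -> smallest class id
  }
  empty <- which(is.na(labels))
  if (length(empty) > 0) {
    coords <- grid_coords(map$grid_shape)
    labelled <- which(!is.na(labels))
    for (k in empty) {
      d2 <- (coords[labelled, 1] - coords[k, 1])^2 +
            (coords[labelled, 2] - coords[k, 2])^2
      # nearest labelled node; grid-distance ties go to the smallest
      # row-major index (labelled is already in increasing index order)
      labels[k] <- labels[labelled[which.min(d2)]]
    }
  }
  out <- map
  out$labels <- labels
  out$label_support <- support
  out
}

#' Predict maturity classes with a labelled map
#'
#' Classifies each case by the label of its best-matching unit. When the map
#' carries a stored normaliser (models trained through [run_benchmark()] do),
#' raw features are normalised with it first.
#'
#' @param object A labelled `topo_map`.
#' @param newdata Tibble with feature columns, or a numeric matrix already on
#'   the map's feature scale.
#' @param normalise Apply the stored normaliser (default: yes, when present).
#' @param ... Unused.
#' @return Integer vector of predicted classes (1..5).
#' @export
predict.topo_map <- function(object, newdata,
                             normalise = !is.null(object$normaliser), ...) {
  if (is.null(object$labels))
    abort("unlabelled-map: label_map() before predicting",
          class = "compostmap_unlabelled")
  if (normalise) {
    if (is.null(object$normaliser)) abort("map carries no normaliser")
    newdata <- apply_normaliser(newdata, object$normaliser)
  }
  object$labels[bmu_indices(object, newdata) + 1L]
}

#' Class regions of a labelled map
#'
#' Partitions the node grid by class label and counts, per class, the number
#' of 4-connected components — a coherence diagnostic: a well-organised map
#' shows each class as one contiguous territory.
#'
#' @param map A labelled `topo_map`.
#' @return Tibble with `class_id`, `n_nodes`, `n_components`, and a `nodes`
#'   list-column of row-major node indices (1-based).
#' @export
class_regions <- function(map) {
  if (is.null(map$labels)) abort("class_regions needs a labelled map")
  rows <- map$grid_shape[1]; cols <- map$grid_shape[2]
  coords <- grid_coords(map$grid_shape)
  # edges between 4-adjacent nodes of the same label
  idx <- seq_len(rows * cols)
  right <- idx[coords[, 2] < cols - 1]
  down <- idx[coords[, 1] < rows - 1]
  from <- c(right, down)
  to <- c(right + 1L, down + cols)
  same <- map$labels[from] == map$labels[to]
  g <- igraph::make_empty_graph(n = rows * cols, directed = FALSE)
  if (any(same)) g <- igraph::add_edges(g, rbind(from[same], to[same]))
  comp <- igraph::components(g)$membership
  purrr::map_dfr(sort(unique(map$labels)), function(cl) {
    nd <- which(map$labels == cl)
    tibble::tibble(class_id = cl, n_nodes = length(nd),
                   n_components = length(unique(comp[nd])),
                   nodes = list(nd))
  })
}
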