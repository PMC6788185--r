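# Kohonen self-organising feature map: a 15x15 grid of prototype vectors
# trained online in two phases — a coarse ordering phase with a wide,
# shrinking neighbourhood, then a fine-tuning phase with a small fixed
# neighbourhood. Grid coordinates are 0-based (row, col), row-major; grid
# distance is Euclidean on those integer coordinates.

#' Two-phase SOFM training schedule
#'
#' Learning rate and neighbourhood radius decay linearly within each phase:
#' phase 1 takes `lr_start` to `lr_mid` and `radius_start` to 1; phase 2
#' takes `lr_mid` to `lr_end` with the radius fixed at `radius_end`.
#'
#' @param phase1_epochs,phase2_epochs Epoch counts (defaults 1000 and 2000).
#' @param lr_start,lr_mid,lr_end Learning-rate waypoints (0.9, 0.1, 0.01).
#' @param radius_start,radius_end Neighbourhood radii in grid units (7.5,
#'   half the default grid, down to 0.5).
#' @param neighbourhood Kernel: `"gaussian"` (`exp(-d^2 / 2r^2)`) or
#'   `"bubble"` (1 within radius, else 0).
#' @param seed Integer seed for the per-epoch case shuffling.
#' @return A `sofm_schedule` list.
#' @export
sofm_schedule <- function(phase1_epochs = 1000L, phase2_epochs = 2000L,
                          lr_start = 0.9, lr_mid = 0.1, lr_end = 0.01,
                          radius_start = 7.5, radius_end = 0.5,
                          neighbourhood = c("gaussian", "bubble"),
                          seed = 1L) {
  neighbourhood <- match.arg(neighbourhood)
  stopifnot(phase1_epochs >= 1, phase2_epochs >= 1,
            lr_end > 0, lr_end <= lr_mid, lr_mid <= lr_start, lr_start <= 1,
            radius_end > 0, radius_end <= radius_start)
  structure(list(phase1_epochs = as.integer(phase1_epochs),
                 phase2_epochs = as.integer(phase2_epochs),
                 lr_start = lr_start, lr_mid = lr_mid, lr_end = lr_end,
                 radius_start = radius_start, radius_end = radius_end,
                 neighbourhood = neighbourhood, seed = as.integer(seed)),
            class = "sofm_schedule")
}

lin_seq <- function(from, to, n) {
  if (n == 1) return(from)
  from + (to - from) * (seq_len(n) - 1) / (n - 1)
}

schedule_vectors <- function(schedule) {
  list(lr = c(lin_seq(schedule$lr_start, schedule$lr_mid, schedule$phase1_epochs),
              lin_seq(schedule$lr_mid, schedule$lr_end, schedule$phase2_epochs)),
       radius = c(lin_seq(schedule$radius_start, 1, schedule$phase1_epochs),
                  rep(schedule$radius_end, schedule$phase2_epochs)))
}

#' Integer grid coordinates of map nodes
#'
#' @param grid_shape Length-2 integer (rows, cols).
#' @return `rows*cols x 2` matrix of 0-based (row, col) pairs in row-major
#'   node order.
#' @export
grid_coords <- function(grid_shape) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  cbind(row = rep(0:(rows - 1), each = cols),
        col = rep(0:(cols - 1), times = rows))
}

#' Initialise a topological map
#'
#' Prototype vectors are drawn uniformly in `[0, 1]^dim`, matching the
#' min-max-normalised feature scale.
#'
#' @param grid_shape Length-2 integer (rows, cols); default `c(15, 15)`.
#' @param dim Feature dimensionality (default 30).
#' @param seed Integer seed.
#' @return A `topo_map` object (unlabelled).
#' @export
#' @examples
#' m <- init_map(c(3, 3), dim = 2, seed = 1)
#' nrow(m$prototypes)
init_map <- function(grid_shape = c(15L, 15L), dim = 30L, seed = 1L) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1), dim >= 1)
  nodes <- prod(grid_shape)
  W <- with_seed(seed, matrix(runif(nodes * dim), nodes, dim))
  new_topo_map(W, as.integer(grid_shape))
}

new_topo_map <- function(prototypes, grid_shape, labels = NULL,
                         label_support = NULL, normaliser = NULL,
                         meta = list()) {
  structure(list(prototypes = prototypes,
                 grid_shape = as.integer(grid_shape),
                 labels = labels, label_support = label_support,
                 normaliser = normaliser, meta = meta),
            class = "topo_map")
}

#' @export
print.topo_map <- function(x, ...) {
  cat(sprintf("<topo_map> %d x %d grid, %d prototypes of dim %d, %s\n",
              x$grid_shape[1], x$grid_shape[2], nrow(x$prototypes),
              ncol(x$prototypes),
              if (is.null(x$labels)) "unlabelled"
              else sprintf("%d classes labelled", length(unique(x$labels)))))
  invisible(x)
}

#' Best-matching unit of a single case
#'
#' The node whose prototype minimises Euclidean distance to `x`; ties go to
#' the smallest row-major linear index.
#'
#' @param map A `topo_map`.
#' @param x Numeric feature vector of the map's dimensionality.
#' @return Integer (row, col), 0-based.
#' @export
bmu <- function(map, x) {
  if (length(x) != ncol(map$prototypes))
    abort(sprintf("dimension mismatch: map dim %d, input dim %d",
                  ncol(map$prototypes), length(x)))
  k <- cpp_bmu_batch(map$prototypes, matrix(as.numeric(x), 1))
  grid_coords(map$grid_shape)[k + 1L, ]
}

# 0-based row-major BMU indices for a case matrix.
bmu_indices <- function(map, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != ncol(map$prototypes))
    abort(sprintf("dimension mismatch: map dim %d, data dim %d",
                  ncol(map$prototypes), ncol(X)))
  cpp_bmu_batch(map$prototypes, X)
}

#' Neighbourhood weight of a node at a grid distance
#'
#' @param kernel `"gaussian"` or `"bubble"`.
#' @param grid_dist Euclidean distance between node coordinates.
#' @param radius Positive neighbourhood radius.
#' @return Weight in \[0, 1\] (vectorised).
#' @export
#' @examples
#' neighbourhood_weight("gaussian", 1, 1)  # exp(-0.5)
neighbourhood_weight <- function(kernel, grid_dist, radius) {
  stopifnot(radius > 0)
  switch(kernel,
         gaussian = exp(-grid_dist^2 / (2 * radius^2)),
         bubble = as.numeric(grid_dist <= radius),
         abort(paste0("unknown kernel: ", kernel)))
}

#' Train a self-organising feature map
#'
#' Online Kohonen training: each epoch visits the training cases in a fresh
#' shuffled order; for each case the BMU is found and every node moves
#' towards the case by `lr * h(node, bmu)`. The per-epoch mean quantization
#' error (case-to-BMU distance at presentation time) is logged in the
#' returned map's `meta$qe`.
#'
#' @param data Tibble with feature columns (rows with
#'   `partition == "train"` are used when a partition column is present) or a
#'   numeric matrix. Features are expected on the normalised \[0, 1\] scale.
#' @param map A `topo_map` to start from, or `NULL` to initialise a
#'   `grid_shape` map from the schedule's seed.
#' @param schedule A [sofm_schedule()].
#' @param grid_shape Grid used when `map` is `NULL`.
#' @return The trained `topo_map`.
#' @export
train_sofm <- function(data, map = NULL, schedule = sofm_schedule(),
                       grid_shape = c(15L, 15L)) {
  X <- as_feature_matrix(if (is.data.frame(data)) partition_rows(data, "train") else data)
  if (nrow(X) == 0) abort("empty training partition")
  if (is.null(map))
    map <- init_map(grid_shape, dim = ncol(X), seed = derive_seed(schedule$seed, 101))
  sv <- schedule_vectors(schedule)
  kernel <- match(schedule$neighbourhood, c("gaussian", "bubble")) - 1L
  res <- cpp_train_sofm(map$prototypes, X, sv$lr, sv$radius,
                        grid_coords(map$grid_shape), kernel,
                        schedule$seed, 1e-12)
  W <- res$prototypes
  colnames(W) <- colnames(X)
  out <- map
  out$prototypes <- W
  out$meta$sofm_schedule <- unclass(schedule)
  out$meta$qe <- res$qe
  out
}

#' Mean quantization error
#'
#' Mean Euclidean distance from each case to its BMU prototype (exact full
#' scan, unlike the online per-epoch log).
#'
#' @inheritParams train_sofm
#' @param map A `topo_map`.
#' @return Non-negative scalar.
#' @export
quantization_error <- function(map, data) {
  X <- as_feature_matrix(if (is.data.frame(data)) data else data)
  if (nrow(X) == 0) abort("quantization_error on empty data")
  mean(cpp_bmu_dist(map$prototypes, X))
}
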