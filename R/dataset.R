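# Training-file assembly: stratified 2:1:1 partitioning and min-max
# normalisation fitted on the training partition only (no leakage into the
# validation or test folds).

#' Stratified 2:1:1 train/validation/test split
#'
#' Assigns every case to `train`, `valid` or `test` so that global partition
#' sizes are exactly 2:1:1 (remainder cases go to train first, then valid,
#' then test) while keeping each class's cases spread near-proportionally
#' across partitions. Deterministic given `seed`.
#'
#' @param features Tibble with a `class_id` column of labels in 1..5.
#' @param seed Integer seed.
#' @return The input tibble with a `partition` column added.
#' @export
#' @examples
#' tbl <- tibble::tibble(x = rnorm(8), class_id = rep(1:2, 4))
#' table(split_211(tbl, seed = 1)$partition)
split_211 <- function(features, seed) {
  n <- nrow(features)
  if (n < 4) abort("too-few-cases: need at least 4 cases for a 2:1:1 split",
                   class = "compostmap_too_few")
  if (!"class_id" %in% names(features) || anyNA(features$class_id))
    abort("split_211 requires a complete class_id column")
  base <- n %/% 4L
  rem <- n %% 4L
  target <- c(train = 2L * base + (rem >= 1L),
              valid = base + (rem >= 2L),
              test = base + (rem >= 3L))
  parts <- c("train", "valid", "test")
  part <- character(n)
  with_seed(seed, {
    for (cl in sort(unique(features$class_id))) {
      idx <- which(features$class_id == cl)
      idx <- idx[sample.int(length(idx))]
      nk <- length(idx)
      q <- nk * c(2, 1, 1) / 4
      fl <- floor(q)
      extra <- nk - sum(fl)
      if (extra > 0) {
        ord <- order(-(q - fl), seq_along(q))  # largest remainder; tie: train, valid, test
        fl[ord[seq_len(extra)]] <- fl[ord[seq_len(extra)]] + 1
      }
      part[idx] <- rep(parts, fl)
    }
    # nudge single cases between partitions until the exact global 2:1:1
    # totals are met (per-stratum rounding can leave a one-or-two case gap)
    repeat {
      counts <- vapply(parts, function(p) sum(part == p), integer(1))
      excess <- counts - target
      if (all(excess == 0)) break
      from <- parts[which.max(excess)]
      to <- parts[which.min(excess)]
      pick <- sample(which(part == from), 1)
      part[pick] <- to
    }
  })
  features$partition <- part
  features
}

#' Fit a per-feature min-max normaliser on the training partition
#'
#' @param features Split tibble (needs `partition == "train"` rows) or any
#'   tibble/matrix when no partition column is present.
#' @return A `compost_normaliser` with per-feature `min` and `max`.
#' @export
fit_normaliser <- function(features) {
  train <- if (is.data.frame(features)) partition_rows(features, "train") else features
  X <- as_feature_matrix(train)
  if (nrow(X) < 2) abort("normaliser needs at least 2 training cases")
  structure(list(min = apply(X, 2, min),
                 max = apply(X, 2, max),
                 features = colnames(X)),
            class = "compost_normaliser")
}

#' Apply (or invert) a min-max normaliser
#'
#' Scales each feature to \[0, 1\] using the training minima and maxima;
#' out-of-range values (validation/test cases beyond the training range) are
#' clipped. Features constant on the training partition map to 0.5.
#'
#' @param features Tibble or matrix of raw features.
#' @param normaliser A [fit_normaliser()] result.
#' @return Object of the same shape with feature columns rescaled.
#' @export
apply_normaliser <- function(features, normaliser) {
  X <- as_feature_matrix(features)
  stopifnot(identical(colnames(X), normaliser$features))
  rng <- normaliser$max - normaliser$min
  Z <- sweep(sweep(X, 2, normaliser$min), 2, ifelse(rng == 0, 1, rng), "/")
  Z[, rng == 0] <- 0.5
  Z <- pmin(pmax(Z, 0), 1)
  if (is.matrix(features)) return(Z)
  features[, colnames(Z)] <- tibble::as_tibble(Z)
  features
}

#' Invert a min-max normaliser
#'
#' Recovers original feature values from normalised ones (exact for values
#' that were inside the training range; constant features return their
#' training value).
#'
#' @inheritParams apply_normaliser
#' @return Object of the same shape on the original feature scale.
#' @export
invert_normaliser <- function(features, normaliser) {
  Z <- as_feature_matrix(features)
  stopifnot(identical(colnames(Z), normaliser$features))
  rng <- normaliser$max - normaliser$min
  X <- sweep(sweep(Z, 2, rng, "*"), 2, normaliser$min, "+")
  X[, rng == 0] <- rep(normaliser$min[rng == 0], each = nrow(X))
  if (is.matrix(features)) return(X)
  features[, colnames(X)] <- tibble::as_tibble(X)
  features
}
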