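# Shared internal helpers: seed scoping, seed derivation, feature-column
# bookkeeping.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so deterministic helpers do not disturb a user's
#' simulation stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Counter-based expansion of one master seed into per-stage (or per-image)
#' seeds: `(master * 69069 + 1234567 * counter) mod (2^31 - 1)`. Keeps every
#' derived seed a valid 32-bit R integer and makes all randomness in a run
#' reproducible from a single number.
#'
#' @param master Integer master seed.
#' @param counter Non-negative integer counter (vectorised).
#' @return Integer seed(s) in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(20190907, 1:3)
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) %% 2147483647 * 69069 +
                1234567 * as.numeric(counter)) %% 2147483647)
}

#' Names of the 30 colour descriptors, in canonical order
#'
#' Ordering is mode (full, then black-excluded) slowest, channel
#' (saturation, luminance, red, green, blue) next, statistic (mean, median,
#' standard deviation) fastest. Serialised models and feature CSVs depend on
#' this order.
#'
#' @return Character vector of length 30.
#' @export
#' @examples
#' feature_names()[1:6]
feature_names <- function() {
  g <- expand.grid(stat = c("mean", "median", "sd"),
                   channel = c("sat", "lum", "r", "g", "b"),
                   mode = c("full", "noblack"),
                   stringsAsFactors = FALSE)
  paste(g$mode, g$channel, g$stat, sep = "_")
}

# Extract the numeric feature matrix from a tibble/data.frame or pass a
# matrix through. Data frames use the canonical 30 columns when present,
# otherwise every numeric column that is not metadata (supports
# low-dimensional toy data).
as_feature_matrix <- function(data) {
  if (is.matrix(data)) {
    storage.mode(data) <- "double"
    return(data)
  }
  stopifnot(is.data.frame(data))
  fn <- feature_names()
  if (all(fn %in% names(data))) {
    cols <- fn
  } else {
    meta <- c("filename", "class_id", "partition", "seed", "id")
    cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], meta)
  }
  if (length(cols) == 0) abort("no feature columns found in data")
  as.matrix(data[, cols, drop = FALSE])
}

# Rows of a split table belonging to one partition; errors or warns per
# caller policy are handled upstream.
partition_rows <- function(data, which) {
  if (!"partition" %in% names(data)) return(data)
  data[data$partition == which, , drop = FALSE]
}
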