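# Synthetic compost-image benchmark. Five maturity classes are emulated as
# class-conditional RGB distributions along a light-straw-to-dark-brown
# gradient; spatial texture is cosmetic (the descriptors downstream are
# per-image channel statistics).

#' Colour specification for one maturity class
#'
#' @param class_id Integer class identifier in 1..5.
#' @param mean_rgb Length-3 numeric, per-channel mean in \[0, 255\].
#' @param sd_rgb Length-3 non-negative numeric, per-channel pixel standard
#'   deviation.
#' @param pixel_corr Spatial smoothing strength in \[0, 1): 0 gives i.i.d.
#'   pixel noise, larger values blend each pixel with a 3x3 neighbourhood
#'   average.
#' @param black_fraction Fraction of pixels in \[0, 1) forced to pure black
#'   (0,0,0), emulating background.
#' @return A `class_colour_spec` list.
#' @export
class_colour_spec <- function(class_id, mean_rgb, sd_rgb,
                              pixel_corr = 0.3, black_fraction = 0.05) {
  stopifnot(length(class_id) == 1, class_id %in% 1:5,
            length(mean_rgb) == 3, all(mean_rgb >= 0 & mean_rgb <= 255),
            length(sd_rgb) == 3, all(sd_rgb >= 0),
            pixel_corr >= 0, pixel_corr < 1,
            black_fraction >= 0, black_fraction < 1)
  structure(list(class_id = as.integer(class_id),
                 mean_rgb = as.numeric(mean_rgb),
                 sd_rgb = as.numeric(sd_rgb),
                 pixel_corr = pixel_corr,
                 black_fraction = black_fraction),
            class = "class_colour_spec")
}

#' Benchmark specification
#'
#' @param classes List of five [class_colour_spec()] objects with distinct
#'   `class_id`.
#' @param n_images_total Total number of images, divided near-equally across
#'   classes (per-class counts differ by at most one).
#' @param image_size Length-2 integer (height, width).
#' @param seed Integer seed governing every image in the benchmark.
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(classes, n_images_total = 3048L,
                           image_size = c(64L, 64L), seed = 20190907L) {
  ids <- vapply(classes, function(cl) cl$class_id, integer(1))
  stopifnot(length(classes) == 5, !anyDuplicated(ids),
            n_images_total >= 5, length(image_size) == 2, all(image_size >= 2))
  structure(list(classes = classes[order(ids)],
                 n_images_total = as.integer(n_images_total),
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' The default synthetic compost benchmark
#'
#' Five classes whose mean RGB traces a linear gradient from light straw
#' (200, 180, 120) to dark brown (60, 40, 25) — maturation darkens and browns
#' the material — with per-channel pixel sd (8, 8, 5), so every channel's
#' between-class mean gap is at least four within-class standard deviations.
#' 5% of pixels per image are pure-black background. 3048 images of 64x64
#' pixels, seed 20190907. These constants are part of the package contract.
#'
#' @return A [benchmark_spec()].
#' @export
#' @examples
#' spec <- default_benchmark_spec()
#' spec$n_images_total
default_benchmark_spec <- function() {
  light <- c(200, 180, 120)
  dark <- c(60, 40, 25)
  classes <- lapply(1:5, function(k) {
    f <- (k - 1) / 4
    class_colour_spec(k, mean_rgb = (1 - f) * light + f * dark,
                      sd_rgb = c(8, 8, 5),
                      pixel_corr = 0.3, black_fraction = 0.05)
  })
  benchmark_spec(classes)
}

#' Per-class image counts for a benchmark
#'
#' Near-equal division of `n` images over `k` classes: the first
#' `n mod k` classes receive one extra image.
#'
#' @param n Total image count.
#' @param k Number of classes.
#' @return Integer vector of length `k` summing to `n`.
#' @export
per_class_counts <- function(n, k = 5L) {
  base <- n %/% k
  as.integer(base + (seq_len(k) <= n %% k))
}

# 3x3 box blur with edge replication; used for cosmetic spatial correlation.
box_blur3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- rbind(m[1, , drop = FALSE], m, m[h, , drop = FALSE])
  p <- cbind(p[, 1, drop = FALSE], p, p[, w, drop = FALSE])
  acc <- matrix(0, h, w)
  for (di in 0:2)
    for (dj in 0:2)
      acc <- acc + p[di + seq_len(h), dj + seq_len(w), drop = FALSE]
  acc / 9
}

#' Generate one synthetic compost image
#'
#' Per-channel Gaussian pixel noise around the class mean, optionally
#' smoothed, clipped and rounded to 8-bit, with exactly
#' `round(black_fraction * h * w)` pixels forced to (0,0,0). Bit-identical
#' output for identical arguments.
#'
#' @param spec A [class_colour_spec()].
#' @param size Length-2 integer (height, width), both at least 2.
#' @param rng_seed Integer seed for this image.
#' @return An `h x w x 3` integer array with values in 0..255.
#' @export
#' @examples
#' img <- generate_image(default_benchmark_spec()$classes[[1]], c(8, 8), 1)
#' dim(img)
generate_image <- function(spec, size, rng_seed) {
  if (length(size) != 2 || any(!is.finite(size)) || any(size < 2))
    abort("bad-dimensions: size must be two integers >= 2",
          class = "compostmap_bad_dimensions")
  h <- as.integer(size[1]); w <- as.integer(size[2])
  with_seed(rng_seed, {
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      z <- matrix(rnorm(h * w, spec$mean_rgb[ch], spec$sd_rgb[ch]), h, w)
      if (spec$pixel_corr > 0)
        z <- (1 - spec$pixel_corr) * z + spec$pixel_corr * box_blur3(z)
      img[, , ch] <- z
    }
    img <- round(pmin(pmax(img, 0), 255))
    n_black <- round(spec$black_fraction * h * w)
    if (n_black > 0) {
      idx <- sample.int(h * w, n_black)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- 0
        img[, , ch] <- plane
      }
    }
    storage.mode(img) <- "integer"
    img
  })
}

#' Generate a benchmark image set on disk
#'
#' Writes PNG images into `class_1` ... `class_5` subdirectories of
#' `out_dir` plus a `manifest.csv` (`filename,class_id,seed`). Per-image
#' seeds are derived from the benchmark seed, so the whole image set is a
#' pure function of the spec.
#'
#' @param spec A [benchmark_spec()].
#' @param out_dir Writable output directory (created if missing).
#' @return The manifest as a tibble, invisibly written to
#'   `out_dir/manifest.csv`.
#' @export
generate_benchmark <- function(spec = default_benchmark_spec(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create output directory: ", out_dir))
  counts <- per_class_counts(spec$n_images_total, length(spec$classes))
  rows <- vector("list", spec$n_images_total)
  i <- 0L
  for (k in seq_along(spec$classes)) {
    cls <- spec$classes[[k]]
    subdir <- file.path(out_dir, paste0("class_", cls$class_id))
    dir.create(subdir, showWarnings = FALSE)
    for (j in seq_len(counts[k])) {
      i <- i + 1L
      s <- derive_seed(spec$seed, i)
      img <- generate_image(cls, spec$image_size, s)
      fn <- file.path(paste0("class_", cls$class_id),
                      sprintf("compost_%05d.png", i))
      png::writePNG(img / 255, file.path(out_dir, fn))
      rows[[i]] <- tibble::tibble(filename = fn, class_id = cls$class_id,
                                  seed = s)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Generate benchmark features in memory
#'
#' Equivalent to [generate_benchmark()] followed by [extract_table()] but
#' without touching disk: each image array is generated and its 30
#' descriptors extracted directly. PNG encoding of 8-bit RGB is lossless, so
#' the two routes give identical feature tables.
#'
#' @inheritParams generate_benchmark
#' @param black_threshold Passed to [extract_features()].
#' @return Tibble with `filename`, the 30 descriptor columns and `class_id`.
#' @export
generate_feature_table <- function(spec = default_benchmark_spec(),
                                   black_threshold = 0) {
  counts <- per_class_counts(spec$n_images_total, length(spec$classes))
  out <- matrix(NA_real_, spec$n_images_total, 30,
                dimnames = list(NULL, feature_names()))
  class_id <- integer(spec$n_images_total)
  fn <- character(spec$n_images_total)
  i <- 0L
  for (k in seq_along(spec$classes)) {
    cls <- spec$classes[[k]]
    for (j in seq_len(counts[k])) {
      i <- i + 1L
      img <- generate_image(cls, spec$image_size, derive_seed(spec$seed, i))
      out[i, ] <- extract_features(img, black_threshold = black_threshold)
      class_id[i] <- cls$class_id
      fn[i] <- file.path(paste0("class_", cls$class_id),
                         sprintf("compost_%05d.png", i))
    }
  }
  dplyr::bind_cols(tibble::tibble(filename = fn),
                   tibble::as_tibble(out),
                   tibble::tibble(class_id = class_id))
}
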