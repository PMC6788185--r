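# The 30-descriptor colour feature scheme: {full, black-excluded} x
# {saturation, luminance, R, G, B} x {mean, median, sd}. A "black" pixel is
# one with max(r,g,b) <= black_threshold (default: exact black), matching the
# synthetic generator's background pixels.

rgb_matrix <- function(rgb) {
  if (is.matrix(rgb)) {
    stopifnot(ncol(rgb) == 3)
    return(rgb)
  }
  stopifnot(length(rgb) == 3)
  matrix(as.numeric(rgb), 1, 3)
}

#' HSV saturation of RGB pixels
#'
#' `(max - min) / max` per pixel, defined as 0 for pure black. Result in
#' \[0, 1\]; saturation-derived descriptors stay on this scale (downstream
#' min-max normalisation makes the scale choice immaterial, but it is fixed).
#'
#' @param rgb Length-3 vector or `n x 3` matrix of channel values in 0..255.
#' @return Numeric vector of saturations.
#' @export
#' @examples
#' channel_saturation(c(200, 100, 50))
channel_saturation <- function(rgb) {
  m <- rgb_matrix(rgb)
  mx <- pmax(m[, 1], m[, 2], m[, 3])
  mn <- pmin(m[, 1], m[, 2], m[, 3])
  ifelse(mx == 0, 0, (mx - mn) / mx)
}

#' BT.601 luminance of RGB pixels
#'
#' `0.299 r + 0.587 g + 0.114 b`, the conventional luma for 8-bit imagery.
#'
#' @inheritParams channel_saturation
#' @return Numeric vector in \[0, 255\].
#' @export
#' @examples
#' channel_luminance(c(100, 200, 50))
channel_luminance <- function(rgb) {
  m <- rgb_matrix(rgb)
  0.299 * m[, 1] + 0.587 * m[, 2] + 0.114 * m[, 3]
}

# Population standard deviation (divide by n); 0 for a single value.
pop_sd <- function(x) {
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Extract the 30 colour descriptors from one image
#'
#' For each of five derived channels (saturation, luminance, red, green,
#' blue) the mean, median and population standard deviation are computed
#' twice: over all pixels ("full" mode) and over pixels that are not black
#' ("noblack" mode), a pixel being black when `max(r,g,b) <= black_threshold`.
#' Medians of even counts average the two central values; sd divides by n.
#'
#' @param image `h x w x 3` numeric array with values in 0..255.
#' @param black_threshold Channel-maximum at or below which a pixel counts as
#'   black. Default 0 (exact black only).
#' @return Named numeric vector of length 30, ordered as [feature_names()].
#' @export
#' @examples
#' img <- array(rep(c(100, 80, 60), each = 4), c(2, 2, 3))
#' extract_features(img)[c("full_r_mean", "full_sat_mean")]
extract_features <- function(image, black_threshold = 0) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3 || d[1] < 1 || d[2] < 1)
    abort("image must be an h x w x 3 array")
  r <- as.numeric(image[, , 1])
  g <- as.numeric(image[, , 2])
  b <- as.numeric(image[, , 3])
  mx <- pmax(r, g, b)
  keep <- mx > black_threshold
  if (!any(keep))
    abort("all-black-image: every pixel is at or below the black threshold",
          class = "compostmap_all_black")
  mn <- pmin(r, g, b)
  sat <- ifelse(mx == 0, 0, (mx - mn) / mx)
  lum <- 0.299 * r + 0.587 * g + 0.114 * b
  chans <- list(sat = sat, lum = lum, r = r, g = g, b = b)
  stats3 <- function(x) c(mean(x), median(x), pop_sd(x))
  vals <- c(
    unlist(lapply(chans, stats3), use.names = FALSE),
    unlist(lapply(chans, function(x) stats3(x[keep])), use.names = FALSE)
  )
  names(vals) <- feature_names()
  vals
}

#' Read an RGB raster image
#'
#' PNG via the png package; JPEG via EBImage when available. Greyscale and
#' alpha-carrying images are promoted/stripped to plain 3-channel RGB.
#'
#' @param path Image file path.
#' @return `h x w x 3` integer array with values in 0..255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      abort("JPEG reading requires the EBImage package")
    a <- EBImage::imageData(EBImage::readImage(path))
    a <- if (length(dim(a)) == 2) aperm(array(a, c(dim(a), 3)), c(2, 1, 3))
         else aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3))
  } else {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2) a <- array(a, c(dim(a), 3))
    if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
    if (dim(a)[3] == 1) a <- array(a, c(dim(a)[1:2], 3))
  }
  img <- round(a * 255)
  storage.mode(img) <- "integer"
  img
}

#' Extract a feature table from a directory of images
#'
#' One row per decodable PNG/JPEG, rows sorted by relative filename for
#' determinism. Class labels come from a manifest (`filename,class_id[,seed]`)
#' when given, otherwise from `class_<k>` subdirectory names; `NA` when
#' neither applies. Undecodable files are skipped with a warning and counted
#' in the `n_skipped` attribute.
#'
#' @param image_dir Directory containing images (searched recursively).
#' @param manifest Optional path to a manifest CSV.
#' @param black_threshold Passed to [extract_features()].
#' @return Tibble with `filename`, 30 descriptor columns and `class_id`.
#' @export
extract_table <- function(image_dir, manifest = NULL, black_threshold = 0) {
  files <- sort(list.files(image_dir, pattern = "\\.(png|jpg|jpeg)$",
                           recursive = TRUE, ignore.case = TRUE))
  if (length(files) == 0) abort(paste0("no decodable images in ", image_dir))
  man <- NULL
  if (!is.null(manifest)) {
    man <- readr::read_csv(manifest, show_col_types = FALSE)
    stopifnot(all(c("filename", "class_id") %in% names(man)))
  }
  rows <- vector("list", length(files))
  skipped <- 0L
  for (i in seq_along(files)) {
    fv <- tryCatch(
      extract_features(read_image(file.path(image_dir, files[i])),
                       black_threshold = black_threshold),
      error = function(e) {
        warn(paste0("skipping undecodable or degenerate image ", files[i],
                    ": ", conditionMessage(e)))
        NULL
      })
    if (is.null(fv)) {
      skipped <- skipped + 1L
      next
    }
    cid <- NA_integer_
    if (!is.null(man)) {
      hit <- match(files[i], man$filename)
      if (!is.na(hit)) cid <- as.integer(man$class_id[hit])
    } else {
      m <- regmatches(files[i], regexpr("class_([0-9]+)", files[i]))
      if (length(m) == 1) cid <- as.integer(sub("class_", "", m))
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(filename = files[i]),
      tibble::as_tibble_row(fv),
      tibble::tibble(class_id = cid))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("no decodable images after skipping failures")
  attr(out, "n_skipped") <- skipped
  out
}
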