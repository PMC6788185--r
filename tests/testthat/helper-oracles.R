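# Independent oracles and small fixture builders used across the suite.
# These re-derive expected values by the most direct route available (per-
# pixel loops, exhaustive search, straight-line replay) and deliberately
# share no code with the implementation.

# Naive per-pixel recomputation of the 30 descriptors for small images.
naive_descriptors <- function(img, black_threshold = 0) {
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- matrix(NA_real_, h * w, 3)
  k <- 0
  for (i in seq_len(h))
    for (j in seq_len(w)) {
      k <- k + 1
      px[k, ] <- c(img[i, j, 1], img[i, j, 2], img[i, j, 3])
    }
  # pixel order is immaterial: all statistics are permutation-invariant
  sat <- apply(px, 1, function(p) {
    mx <- max(p); if (mx == 0) 0 else (mx - min(p)) / mx
  })
  lum <- apply(px, 1, function(p) 0.299 * p[1] + 0.587 * p[2] + 0.114 * p[3])
  keep <- apply(px, 1, max) > black_threshold
  med <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  psd <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / length(x))
  chans <- list(sat, lum, px[, 1], px[, 2], px[, 3])
  out <- c()
  for (mode in 1:2)
    for (ch in chans) {
      v <- if (mode == 1) ch else ch[keep]
      out <- c(out, sum(v) / length(v), med(v), psd(v))
    }
  out
}

# Exhaustive best-matching unit: scan every node, smallest distance, ties to
# the smallest row-major index.
brute_bmu <- function(W, x) {
  d <- apply(W, 1, function(w) sum((w - x)^2))
  which(d == min(d))[1]
}

# Straight-line replay of the LVQ1 update sequence with shuffling off.
replay_lvq1 <- function(W, wlab, X, y, lrs) {
  for (a in lrs)
    for (i in seq_len(nrow(X))) {
      b <- brute_bmu(W, X[i, ])
      s <- if (wlab[b] == y[i]) a else -a
      W[b, ] <- W[b, ] + s * (X[i, ] - W[b, ])
    }
  W
}

# A small, quickly separable benchmark spec for pipeline-level tests.
tiny_benchmark <- function(n = 50, size = c(16, 16), seed = 7,
                           sd_rgb = c(8, 8, 5), pixel_corr = 0.3) {
  light <- c(200, 180, 120); dark <- c(60, 40, 25)
  classes <- lapply(1:5, function(k) {
    f <- (k - 1) / 4
    class_colour_spec(k, (1 - f) * light + f * dark, sd_rgb,
                      pixel_corr = pixel_corr, black_fraction = 0.05)
  })
  benchmark_spec(classes, n_images_total = n, image_size = size, seed = seed)
}

# Fast schedules for desk-scale pipeline tests.
tiny_sofm <- function(seed = 1) {
  sofm_schedule(phase1_epochs = 15, phase2_epochs = 30,
                radius_start = 3.5, seed = seed)
}
tiny_lvq <- function(seed = 1, epochs = 40) lvq_schedule(epochs = epochs, seed = seed)

# Run the whole pipeline on a tiny benchmark with a small map; returns the
# evaluation report's tidy tibble plus the model.
tiny_pipeline <- function(spec, master_seed = 1, grid = c(5, 5)) {
  tbl <- generate_feature_table(spec)
  sp <- split_211(tbl, seed = derive_seed(master_seed, 2))
  norm <- fit_normaliser(sp)
  spn <- apply_normaliser(sp, norm)
  m <- init_map(grid, 30, seed = derive_seed(master_seed, 3))
  m <- train_sofm(spn, m, tiny_sofm(seed = derive_seed(master_seed, 4)))
  m <- label_map(spn, m)
  m <- train_lvq1(spn, m, tiny_lvq(seed = derive_seed(master_seed, 5)))
  m$normaliser <- norm
  list(model = m, report = evaluate_model(sp, m), split = sp)
}
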