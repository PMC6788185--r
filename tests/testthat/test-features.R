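test_that("saturation and luminance follow the stated conventions", {
  expect_equal(channel_saturation(c(128, 128, 128)), 0)
  expect_equal(channel_saturation(c(255, 0, 0)), 1)
  expect_equal(channel_saturation(c(200, 100, 50)), 0.75)  # (200-50)/200
  expect_equal(channel_saturation(c(0, 0, 0)), 0)          # black pinned to 0
  expect_equal(channel_luminance(c(0, 0, 0)), 0)
  expect_equal(channel_luminance(c(255, 255, 255)), 255)   # weights sum to 1
  expect_equal(channel_luminance(c(100, 200, 50)), 153)    # 29.9 + 117.4 + 5.7
  # vectorised over pixel matrices
  m <- rbind(c(200, 100, 50), c(0, 0, 0))
  expect_equal(channel_saturation(m), c(0.75, 0))
})

test_that("descriptor vector has the canonical 30-entry layout", {
  img <- generate_image(default_benchmark_spec()$classes[[2]], c(8, 8), 1)
  fv <- extract_features(img)
  expect_length(fv, 30)
  expect_identical(names(fv), feature_names())
  expect_true(all(fv[grep("_sat_", names(fv))] >= 0))
  expect_true(all(fv[grep("_sat_(mean|median)", names(fv))] <= 1))
  expect_true(all(fv[grep("_sd$", names(fv))] >= 0))
})

test_that("uniform image gives identical full/noblack blocks and zero sds", {
  img <- array(rep(c(100, 80, 60), each = 12), c(3, 4, 3))
  fv <- extract_features(img)
  expect_equal(unname(fv["full_r_mean"]), 100)
  expect_equal(unname(fv["full_r_median"]), 100)
  expect_equal(unname(fv["full_r_sd"]), 0)
  expect_equal(unname(fv[1:15]), unname(fv[16:30]))
})

test_that("black-excluded mode drops exact-black pixels", {
  img <- array(0, c(2, 1, 3))
  img[2, 1, ] <- c(200, 100, 50)
  fv <- extract_features(img, black_threshold = 0)
  expect_equal(unname(fv["full_r_mean"]), 100)
  expect_equal(unname(fv["noblack_r_mean"]), 200)
  expect_equal(unname(fv["full_r_sd"]), 100)  # population sd over {0, 200}
  expect_equal(unname(fv["noblack_r_sd"]), 0)
  # no black pixels -> modes coincide entry-for-entry
  img2 <- generate_image(class_colour_spec(1, c(150, 120, 90), c(5, 5, 5),
                                           black_fraction = 0), c(6, 6), 2)
  fv2 <- extract_features(img2)
  expect_equal(unname(fv2[1:15]), unname(fv2[16:30]))
})

test_that("an entirely black image is rejected, not silently summarised", {
  expect_error(extract_features(array(0L, c(3, 3, 3))),
               class = "compostmap_all_black")
  expect_error(extract_features(array(2L, c(3, 3, 3)), black_threshold = 5),
               class = "compostmap_all_black")
})

test_that("descriptors match a naive per-pixel oracle on small images", {
  set.seed(31)
  for (rep in 1:20) {
    h <- sample(2:4, 1); w <- sample(2:4, 1)
    img <- array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
    thr <- sample(c(0, 0, 10), 1)
    expected <- tryCatch(naive_descriptors(img, thr), error = function(e) NULL)
    if (all(pmax(img[, , 1], img[, , 2], img[, , 3]) <= thr)) next
    expect_equal(unname(extract_features(img, thr)), expected, tolerance = 1e-12)
  }
})

test_that("descriptors are invariant under 2x2 pixel replication", {
  img <- generate_image(default_benchmark_spec()$classes[[4]], c(5, 7), 9)
  big <- img[rep(seq_len(5), each = 2), rep(seq_len(7), each = 2), ]
  expect_equal(extract_features(big), extract_features(img), tolerance = 1e-12)
})

test_that("extract_table reproduces the in-memory feature route", {
  dir <- withr::local_tempdir()
  spec <- tiny_benchmark(n = 10, size = c(8, 8), seed = 5)
  generate_benchmark(spec, dir)
  tbl_disk <- extract_table(dir, manifest = file.path(dir, "manifest.csv"))
  tbl_mem <- generate_feature_table(spec)
  expect_equal(nrow(tbl_disk), 10)
  expect_identical(names(tbl_disk), c("filename", feature_names(), "class_id"))
  expect_equal(as.data.frame(tbl_disk), as.data.frame(tbl_mem),
               tolerance = 1e-12, ignore_attr = TRUE)
  # determinism on re-read, class ids from subdirectories when no manifest
  expect_identical(tbl_disk, extract_table(dir, file.path(dir, "manifest.csv")))
  tbl_nodir <- extract_table(dir)
  expect_equal(tbl_nodir$class_id, tbl_disk$class_id)
})

test_that("extract_table skips undecodable files and rejects empty dirs", {
  dir <- withr::local_tempdir()
  expect_error(extract_table(dir), "no decodable images")
  generate_benchmark(tiny_benchmark(n = 5, size = c(4, 4)), dir)
  writeLines("not a png", file.path(dir, "class_1", "junk.png"))
  expect_warning(tbl <- extract_table(dir), "skipping")
  expect_equal(nrow(tbl), 5)
  expect_equal(attr(tbl, "n_skipped"), 1L)
})
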