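test_that("lvq1_update attracts same-class and repels other-class cases", {
  expect_equal(lvq1_update(c(0, 0), 1, c(1, 0), 1, 0.5), c(0.5, 0))
  expect_equal(lvq1_update(c(0, 0), 1, c(1, 0), 2, 0.5), c(-0.5, 0))
  expect_equal(lvq1_update(c(0.4, 0.2), 3, c(0.9, 0.1), 3, 1e-9),
               c(0.4, 0.2), tolerance = 1e-8)
  # distance contracts by (1 - lr) under attraction, grows by (1 + lr) under repulsion
  set.seed(14)
  for (rep in 1:25) {
    w <- rnorm(6); x <- rnorm(6); lr <- runif(1, 0.01, 0.9)
    d0 <- sqrt(sum((w - x)^2))
    da <- sqrt(sum((lvq1_update(w, 1, x, 1, lr) - x)^2))
    dr <- sqrt(sum((lvq1_update(w, 1, x, 2, lr) - x)^2))
    expect_equal(da, (1 - lr) * d0, tolerance = 1e-12)
    expect_equal(dr, (1 + lr) * d0, tolerance = 1e-12)
  }
})

lvq_fixture <- function() {
  # 2 prototypes, 4 training cases, 2 validation cases in 2-D
  map <- structure(list(prototypes = rbind(c(0.2, 0.2), c(0.8, 0.8)),
                        grid_shape = c(2L, 1L), labels = c(1L, 2L),
                        meta = list()), class = "topo_map")
  data <- tibble::tibble(
    x1 = c(0.1, 0.3, 0.7, 0.9, 0.2, 0.8),
    x2 = c(0.2, 0.1, 0.9, 0.8, 0.15, 0.85),
    class_id = c(1L, 2L, 2L, 1L, 1L, 2L),  # two deliberate label clashes
    partition = c(rep("train", 4), rep("valid", 2)))
  list(map = map, data = data)
}

test_that("train_lvq1 equals a straight-line replay of the update sequence", {
  fx <- lvq_fixture()
  sch <- lvq_schedule(epochs = 2, lr_start = 0.9, lr_end = 0.01,
                      shuffle = FALSE, seed = 1)
  out <- train_lvq1(fx$data, fx$map, sch)
  train <- fx$data[fx$data$partition == "train", ]
  expected <- replay_lvq1(fx$map$prototypes, fx$map$labels,
                          cbind(train$x1, train$x2), train$class_id,
                          lrs = c(0.9, 0.01))
  expect_equal(out$meta$lvq$final_prototypes, expected, tolerance = 1e-12)
})

test_that("a lone matching prototype contracts onto its case", {
  map <- structure(list(prototypes = rbind(c(0.9, 0.1)), grid_shape = c(1L, 1L),
                        labels = 1L, meta = list()), class = "topo_map")
  data <- tibble::tibble(x1 = c(0.3, 0.3), x2 = c(0.6, 0.6),
                         class_id = c(1L, 1L),
                         partition = c("train", "valid"))
  out <- train_lvq1(data, map, lvq_schedule(epochs = 3000, seed = 2))
  expect_equal(unname(out$meta$lvq$final_prototypes[1, ]), c(0.3, 0.6),
               tolerance = 1e-6)
  expect_equal(max(unlist(out$meta$lvq$val_quality)), 1)
})

test_that("training is deterministic and keeps the best validation epoch", {
  fx <- lvq_fixture()
  sch <- lvq_schedule(epochs = 40, shuffle = FALSE, seed = 3)
  a <- train_lvq1(fx$data, fx$map, sch)
  b <- train_lvq1(fx$data, fx$map, sch)
  expect_identical(a$prototypes, b$prototypes)
  # with shuffling on, a fixed seed is still bit-deterministic
  sch2 <- lvq_schedule(epochs = 40, shuffle = TRUE, seed = 3)
  expect_identical(train_lvq1(fx$data, fx$map, sch2)$prototypes,
                   train_lvq1(fx$data, fx$map, sch2)$prototypes)
  vq <- unlist(a$meta$lvq$val_quality)
  expect_equal(vq[a$meta$lvq$best_epoch], max(vq))
  expect_equal(a$meta$lvq$best_epoch, which.max(vq))  # ties -> earliest
  expect_gte(vq[a$meta$lvq$best_epoch], vq[length(vq)])
})

test_that("perfectly separated data with class-mean prototypes stays perfect", {
  set.seed(8)
  n <- 30
  X <- rbind(cbind(rnorm(n, 0.2, 0.03), rnorm(n, 0.2, 0.03)),
             cbind(rnorm(n, 0.8, 0.03), rnorm(n, 0.8, 0.03)))
  lab <- rep(1:2, each = n)
  data <- tibble::tibble(x1 = X[, 1], x2 = X[, 2], class_id = lab,
                         partition = rep(c("train", "valid"), n))
  map <- structure(list(prototypes = rbind(c(0.2, 0.2), c(0.8, 0.8)),
                        grid_shape = c(2L, 1L), labels = c(1L, 2L),
                        meta = list()), class = "topo_map")
  out <- train_lvq1(data, map, lvq_schedule(epochs = 30, seed = 4))
  expect_equal(max(unlist(out$meta$lvq$val_quality)), 1)
  # attraction only: prototypes stay inside their class's bounding box
  for (k in 1:2) {
    cls <- X[lab == k, ]
    expect_true(all(out$prototypes[k, ] >= apply(cls, 2, min) - 1e-12))
    expect_true(all(out$prototypes[k, ] <= apply(cls, 2, max) + 1e-12))
  }
})

test_that("unlabelled maps and missing partitions are rejected", {
  fx <- lvq_fixture()
  bad <- fx$map; bad$labels <- NULL
  expect_error(train_lvq1(fx$data, bad, lvq_schedule(epochs = 2)),
               class = "compostmap_unlabelled")
  no_valid <- fx$data[fx$data$partition != "valid", ]
  expect_error(train_lvq1(no_valid, fx$map, lvq_schedule(epochs = 2)),
               "validation")
})

test_that("early stopping halts after the stated patience", {
  fx <- lvq_fixture()
  out <- train_lvq1(fx$data, fx$map,
                    lvq_schedule(epochs = 500, seed = 5,
                                 early_stop_patience = 10))
  vq <- unlist(out$meta$lvq$val_quality)
  expect_lt(length(vq), 500)
  expect_equal(length(vq), out$meta$lvq$best_epoch + 10)
})
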