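test_that("map initialisation is seeded, shaped and bounded", {
  m <- init_map(c(15, 15), dim = 30, seed = 8)
  expect_equal(dim(m$prototypes), c(225L, 30L))
  expect_true(all(m$prototypes >= 0 & m$prototypes <= 1))
  expect_identical(m$prototypes, init_map(c(15, 15), 30, seed = 8)$prototypes)
  expect_equal(dim(init_map(c(1, 1), dim = 3, seed = 1)$prototypes), c(1L, 3L))
})

test_that("bmu matches exact-prototype and tie-break contracts", {
  m <- init_map(c(3, 3), dim = 4, seed = 2)
  x <- m$prototypes[8, ]  # node (2,1) in 0-based row-major
  expect_equal(unname(bmu(m, x)), c(2, 1))
  # two equidistant prototypes: the smaller row-major index wins
  m2 <- init_map(c(2, 2), dim = 2, seed = 1)
  m2$prototypes <- rbind(c(5, 5), c(0, 1), c(1, 0), c(5, -5))
  expect_equal(unname(bmu(m2, c(0, 0))), c(0, 1))  # linear index 1 beats 2
  expect_error(bmu(m, c(1, 2)), "dimension mismatch")
})

test_that("bmu agrees with the exhaustive oracle on random instances", {
  set.seed(77)
  for (rep in 1:200) {
    nodes <- sample(2:12, 1); d <- sample(1:6, 1)
    W <- matrix(rnorm(nodes * d), nodes, d)
    x <- rnorm(d)
    m <- structure(list(prototypes = W, grid_shape = c(nodes, 1L)),
                   class = "topo_map")
    coords <- grid_coords(c(nodes, 1))
    got <- bmu(m, x)
    expect_equal(unname(got), unname(coords[brute_bmu(W, x), ]))
  }
})

test_that("neighbourhood kernels follow their closed forms", {
  expect_equal(neighbourhood_weight("gaussian", 0, 3), 1)
  expect_equal(neighbourhood_weight("gaussian", 2, 2), exp(-0.5))
  expect_equal(neighbourhood_weight("bubble", 2, 1), 0)
  expect_equal(neighbourhood_weight("bubble", c(0.5, 1, 1.5), 1), c(1, 1, 0))
})

test_that("training contracts: fixed point, identity at lr=0-limit, bounds", {
  # single data point: all prototypes collapse onto it (gaussian kernel)
  x <- matrix(c(0.3, 0.7), 1)
  m <- init_map(c(3, 3), dim = 2, seed = 4)
  sch <- sofm_schedule(phase1_epochs = 200, phase2_epochs = 1000,
                       radius_start = 3, radius_end = 2, seed = 1)
  trained <- train_sofm(x, m, sch)
  expect_true(all(abs(sweep(trained$prototypes, 2, as.numeric(x))) < 1e-3))
  # training data in [0,1]^d keeps prototypes in [0,1]^d (convex updates)
  X <- matrix(runif(200), 100, 2)
  t2 <- train_sofm(X, init_map(c(4, 4), 2, seed = 2),
                   sofm_schedule(phase1_epochs = 10, phase2_epochs = 10,
                                 radius_start = 2, seed = 3))
  expect_true(all(t2$prototypes >= 0 & t2$prototypes <= 1))
  # near-zero learning rate leaves the map essentially unchanged
  sch0 <- sofm_schedule(phase1_epochs = 5, phase2_epochs = 5,
                        lr_start = 1e-12, lr_mid = 1e-12, lr_end = 1e-13,
                        radius_start = 2, seed = 1)
  t3 <- train_sofm(X, m, sch0)
  expect_equal(t3$prototypes, m$prototypes, tolerance = 1e-9)
})

test_that("two separated clusters on a 2x1 grid recover the cluster means", {
  set.seed(123)
  n <- 60
  X <- rbind(cbind(rnorm(n, 0.2, 0.05), rnorm(n, 0.2, 0.05)),
             cbind(rnorm(n, 0.8, 0.05), rnorm(n, 0.8, 0.05)))
  means <- rbind(colMeans(X[1:n, ]), colMeans(X[n + 1:n, ]))
  m <- train_sofm(X, init_map(c(2, 1), 2, seed = 5),
                  sofm_schedule(phase1_epochs = 50, phase2_epochs = 150,
                                radius_start = 1, radius_end = 0.1, seed = 6))
  # match each prototype to its nearest cluster mean
  assign <- apply(m$prototypes, 1, function(w)
    which.min(colSums((t(means) - w)^2)))
  expect_setequal(assign, 1:2)
  sem <- 0.05 / sqrt(n)
  for (k in 1:2)
    expect_true(all(abs(m$prototypes[which(assign == k), ] - means[k, ]) < 3 * sem))
})

test_that("a 1x5 map trained on a line orders its nodes along the line", {
  set.seed(11)
  t <- runif(150)
  X <- cbind(t, t)
  m <- train_sofm(X, init_map(c(1, 5), 2, seed = 3),
                  sofm_schedule(phase1_epochs = 80, phase2_epochs = 120,
                                radius_start = 2.5, seed = 9))
  probe <- cbind(seq(0.05, 0.95, length.out = 20), seq(0.05, 0.95, length.out = 20))
  idx <- apply(probe, 1, function(x) brute_bmu(m$prototypes, x))
  d <- diff(idx)
  expect_true(all(d >= 0) || all(d <= 0))
})

test_that("online quantization error declines through phase 2 across seeds", {
  set.seed(21)
  X <- matrix(runif(400), 200, 2)
  deltas <- vapply(1:6, function(s) {
    m <- train_sofm(X, init_map(c(4, 4), 2, seed = s),
                    sofm_schedule(phase1_epochs = 20, phase2_epochs = 40,
                                  radius_start = 2, seed = s + 100))
    qe <- m$meta$qe
    qe[length(qe)] - qe[21]  # final epoch minus first phase-2 epoch
  }, numeric(1))
  expect_lte(mean(deltas), 0)
})

test_that("quantization_error matches a brute-force recomputation", {
  set.seed(5)
  W <- matrix(runif(20), 10, 2)
  m <- structure(list(prototypes = W, grid_shape = c(10L, 1L)),
                 class = "topo_map")
  X <- matrix(runif(30), 15, 2)
  brute <- mean(apply(X, 1, function(x)
    sqrt(min(rowSums(sweep(W, 2, x)^2)))))
  expect_equal(quantization_error(m, X), brute, tolerance = 1e-12)
  # data equal to a subset of prototypes -> zero
  expect_equal(quantization_error(m, W[c(2, 5), ]), 0)
  expect_error(quantization_error(m, X[0, , drop = FALSE]), "empty")
})
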