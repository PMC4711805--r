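test_that("density estimate matches brute-force kernel summation", {
  # zero-distance single point: f = K(0)/h^d = c_kd/h^d
  k4 <- kernel_spec("gaussian", 4)
  x <- c(1, 2, 3, 4)
  expect_equal(
    density_estimate(x, matrix(x, 1), "gaussian", bandwidth = 2),
    k4$c_kd / 2^4
  )

  # 1-d collinear toy against direct summation
  data1 <- matrix(c(-1, 0, 2), ncol = 1)
  h <- 0.7
  brute <- sum((2 * pi)^(-1 / 2) * exp(-((0.3 - data1[, 1]) / h)^2 / 2)) / (3 * h)
  expect_equal(
    density_estimate(0.3, data1, kernel_spec("gaussian", 1), h),
    brute,
    tolerance = 1e-12
  )

  # flat kernel covering all points: value depends only on n and h
  d <- matrix(c(0, 0, 1, 0, -1, 0, 0, 2), ncol = 2, byrow = TRUE)
  kf <- kernel_spec("flat", 2)
  expect_equal(
    density_estimate(c(0, 0.5), d, kf, bandwidth = 10),
    4 * kf$c_kd / (4 * 10^2)
  )

  expect_error(
    density_estimate(0, matrix(numeric(), ncol = 1), "gaussian", 1),
    class = "islandshift_input_error"
  )
})

test_that("mean-shift vector equals the shadow-weighted mean minus x", {
  # x at the centroid, flat kernel covering all -> zero shift
  d <- rbind(c(1, 0, 0, 0), c(-1, 0, 0, 0), c(0, 2, 0, 0), c(0, -2, 0, 0))
  expect_equal(
    mean_shift_vector(c(0, 0, 0, 0), d, "flat", bandwidth = 10),
    c(0, 0, 0, 0)
  )

  # single data point: shift lands exactly on it
  p <- c(3, -1, 2, 0)
  expect_equal(
    mean_shift_vector(c(0, 0, 0, 0), matrix(p, 1), "gaussian", 1),
    p
  )

  # random 10-point set against term-by-term evaluation
  set.seed(7)
  data <- matrix(rnorm(40), 10)
  x <- rnorm(4)
  w <- exp(-colSums((t(data) - x)^2) / 2) / 2 # g for gaussian, h = 1
  expected <- colSums(data * w) / sum(w) - x
  expect_equal(mean_shift_vector(x, data, "gaussian", 1), expected, tolerance = 1e-12)

  # isolated under the flat kernel
  expect_error(
    mean_shift_vector(c(100, 100, 100, 100), d, "flat", bandwidth = 1),
    class = "islandshift_isolated_point"
  )
})

test_that("mode seeking converges to the density maximum", {
  # start at an existing mode: symmetric pair centroid, zero shift
  d <- matrix(c(-1, 1), ncol = 1)
  r <- shift_to_mode(0, d, kernel_spec("gaussian", 1), bandwidth = 5)
  expect_true(r$converged)
  expect_equal(r$mode, 0, tolerance = 1e-9)
  expect_lte(r$iterations, 1L)

  # locality: a start in blob A converges inside blob A's hull
  set.seed(3)
  a <- matrix(rnorm(20, sd = 0.2), ncol = 4)
  b <- matrix(rnorm(20, sd = 0.2), ncol = 4) + 50
  r2 <- shift_to_mode(a[1, ], rbind(a, b), "gaussian", bandwidth = 1)
  expect_true(all(r2$mode > apply(a, 2, min) - 0.2 & r2$mode < apply(a, 2, max) + 0.2))

  # 1-d mixture: mode agrees with a dense grid search over the density
  set.seed(9)
  pts <- matrix(c(rnorm(15, 0, 0.5), rnorm(5, 4, 0.5)), ncol = 1)
  h <- 0.8
  grid <- seq(-2, 2, by = 1e-3)
  dens <- vapply(grid, density_estimate,
    numeric(1),
    data = pts, kernel = kernel_spec("gaussian", 1), bandwidth = h
  )
  r3 <- shift_to_mode(-0.5, pts, kernel_spec("gaussian", 1), h, epsilon = 1e-9)
  expect_lt(abs(r3$mode - grid[which.max(dens)]), 2e-3)
})

test_that("gaussian trajectories are monotone density ascents", {
  set.seed(11)
  for (rep in 1:5) {
    data <- blob_instance(30, matrix(runif(8, 0, 20), 2), sd = 1.5)
    k <- kernel_spec("gaussian", ncol(data))
    x <- data[sample(nrow(data), 1), ]
    f_prev <- density_estimate(x, data, k, 2)
    for (i in 1:100) {
      m <- mean_shift_vector(x, data, k, 2)
      x <- x + m
      f <- density_estimate(x, data, k, 2)
      expect_gte(f, f_prev - 1e-9)
      f_prev <- f
      if (sqrt(sum(m^2)) < 1e-6) break
    }
  }
})

test_that("mode grouping is single linkage with strict radius", {
  expect_equal(cluster_modes(matrix(1, 4, 2), 0.1), rep(1L, 4))
  expect_equal(
    cluster_modes(rbind(c(0, 0), c(100, 0)), 0.1),
    c(1L, 2L)
  )
  # chain of modes each radius/2 apart merges transitively into one cluster
  chain <- cbind(seq(0, 2, by = 0.05), 0)
  expect_equal(cluster_modes(chain, 0.1), rep(1L, nrow(chain)))
  # just past the radius: no link
  expect_equal(cluster_modes(rbind(0, 0.1), 0.1), c(1L, 2L))
})

test_that("clustering is a partition with first-occurrence labels", {
  set.seed(5)
  x <- rbind(
    matrix(rnorm(40, sd = 0.3), ncol = 4) + 20,
    matrix(rnorm(40, sd = 0.3), ncol = 4)
  )
  fit <- mean_shift(x, bandwidth = 2)
  expect_equal(fit$n_clusters, 2L)
  expect_equal(length(fit$labels), nrow(x))
  expect_equal(sort(unique(fit$labels)), seq_len(fit$n_clusters))
  expect_equal(fit$labels[1], 1L) # first point defines cluster 1
  expect_equal(fit$labels, rep(c(1L, 2L), each = 10))
  expect_true(all(fit$converged))

  td <- tidy(fit)
  expect_equal(nrow(td), 20L)
  expect_equal(td$cluster, fit$labels)
  gl <- glance(fit)
  expect_equal(gl$n_clusters, 2L)
})

test_that("bandwidth limits give one cluster and n clusters", {
  set.seed(8)
  x <- matrix(runif(40, 0, 10), ncol = 4)
  # h far beyond the data diameter: everything merges (flat kernel covers all)
  expect_equal(mean_shift(x, bandwidth = 1e4, kernel = "flat")$n_clusters, 1L)
  expect_equal(mean_shift(x, bandwidth = 1e4, kernel = "gaussian")$n_clusters, 1L)
  # h -> 0 with distinct points: every point its own mode
  expect_equal(mean_shift(x, bandwidth = 1e-4)$n_clusters, nrow(x))
  # n identical points form a single cluster
  same <- matrix(2, 6, 4)
  expect_equal(mean_shift(same, bandwidth = 1)$n_clusters, 1L)
})

test_that("the partition is invariant under input permutation", {
  set.seed(13)
  x <- blob_instance(40, matrix(c(0, 0, 0, 0, 15, 15, 15, 15, 0, 15, 0, 15), 3, byrow = TRUE))
  fit <- mean_shift(x, bandwidth = 2)
  perm <- sample(nrow(x))
  fit_p <- mean_shift(x[perm, ], bandwidth = 2)
  expect_equal(
    canonical_labels(fit_p$labels),
    canonical_labels(fit$labels[perm])
  )
})

test_that("cluster masses sum to the genome length", {
  w <- partition_windows(repeat_genome(123456), 10000)
  labels <- rep(c(1L, 2L), length.out = nrow(w))
  cm <- cluster_masses(labels, w$width)
  expect_equal(sum(cm$mass), 123456L)
})
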