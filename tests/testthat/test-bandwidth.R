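test_that("deviation band arithmetic is exact", {
  # host windows with A-sums {10,10,10,30}: mean 15, population sd sqrt(75)
  host <- windows_from_counts(cbind(c(10, 10, 10, 30), 20, 20, 20))
  stats <- window_stats(host)
  expect_equal(unname(stats$mean["a"]), 15)
  expect_equal(unname(stats$sd["a"]), sqrt(75))

  # fragment at the host mean deviates nowhere
  expect_false(composition_deviates(stats$mean, stats, std_coeff = 1))
  # A-sum 25 > 15 + sqrt(75) = 23.66: deviates
  expect_true(composition_deviates(c(25, 20, 20, 20), stats, std_coeff = 1))
  # same fragment inside a wider band (c = 2): no deviation
  expect_false(composition_deviates(c(25, 20, 20, 20), stats, std_coeff = 2))
  # a two-sd excursion on one nucleotide is enough under the "any" quantifier
  s2 <- window_stats(windows_from_counts(cbind(c(10, 20), c(10, 20), c(10, 20), c(10, 20))))
  expect_true(composition_deviates(c(15 + 2 * 5, 15, 15, 15), s2, std_coeff = 1))
  # but not under "all"
  expect_false(
    composition_deviates(c(15 + 2 * 5, 15, 15, 15), s2, std_coeff = 1, quantifier = "all")
  )
  expect_error(composition_deviates(c(1, 1, 1, 1), stats, std_coeff = 0.5),
    class = "islandshift_input_error"
  )
})

test_that("compositional dissimilarity is the L1 mass fraction", {
  a <- c(50, 20, 15, 15)
  expect_equal(composition_dissimilarity(a, a, 100), 0)
  expect_equal(
    composition_dissimilarity(c(100, 0, 0, 0), c(0, 100, 0, 0), 100),
    1.0
  )
  expect_equal(
    composition_dissimilarity(c(50, 20, 15, 15), c(40, 30, 15, 15), 100),
    0.10
  )
  # symmetry
  expect_equal(
    composition_dissimilarity(c(40, 30, 15, 15), c(50, 20, 15, 15), 100),
    0.10
  )
})

test_that("fragment selection demands deviation and mutual dissimilarity", {
  host_sim <- simulate_host_genome(300000, background_gc = 0.5, seed = 21)
  host_w <- partition_windows(host_sim$genome, 50000)
  stats <- window_stats(host_w)

  # a pool that is a copy of the host offers nothing deviant at large c
  self_pool <- donor_pool(list(genome_sequence("copy", host_sim$genome$sequence)))
  expect_error(
    select_artificial_fragments(self_pool, stats, 50000, std_coeff = 4, n_fragments = 2),
    class = "islandshift_insufficient_donors"
  )

  # one AT-rich and one GC-rich donor vs a balanced host: one fragment each
  pool <- simulate_donor_pool(c(0.30, 0.70), genome_length = 150000, seed = 22)
  frags <- select_artificial_fragments(pool, stats, 50000, n_fragments = 2, seed = 1)
  expect_equal(nrow(frags), 2L)
  expect_setequal(frags$donor_id, c("donor_gc30", "donor_gc70"))
  expect_true(all(composition_deviates(frags, stats)))
  expect_gt(
    composition_dissimilarity(
      unlist(frags[1, c("a", "t", "c", "g")]),
      unlist(frags[2, c("a", "t", "c", "g")]), 50000
    ),
    0.075
  )

  # the error message names how many fragments were found
  expect_error(
    select_artificial_fragments(pool, stats, 50000, n_fragments = 6, seed = 1),
    "only 2 of 6"
  )

  # reproducible under seed; a different seed may scan in a different order
  f1 <- select_artificial_fragments(pool, stats, 50000, n_fragments = 2, seed = 9)
  f2 <- select_artificial_fragments(pool, stats, 50000, n_fragments = 2, seed = 9)
  expect_identical(f1, f2)
})

test_that("separation predicate is strict about fragment isolation", {
  expect_false(is_separated(rep(1L, 6), artificial_idx = 5:6))
  expect_true(is_separated(c(1L, 1L, 1L, 1L, 2L, 3L), artificial_idx = 5:6))
  # two fragments sharing a (host-free) cluster fail the strict reading
  expect_false(is_separated(c(1L, 1L, 1L, 1L, 2L, 2L), artificial_idx = 5:6))
  # ... but pass the relaxed one
  expect_true(is_separated(c(1L, 1L, 1L, 1L, 2L, 2L), artificial_idx = 5:6, strict = FALSE))
  # a fragment co-clustered with a host window always fails
  expect_false(is_separated(c(1L, 1L, 2L, 1L, 2L, 3L), artificial_idx = 5:6))
})

test_that("bandwidth search returns the largest separating value on its grid", {
  set.seed(31)
  host <- matrix(rnorm(80, sd = 0.5), ncol = 4) # tight blob at the origin
  frags <- rbind(rep(40, 4), rep(-40, 4))

  # fragments far beyond the host diameter separate at h_init: no decrements
  far <- find_bandwidth(host, frags, h_init = max(dist(host)))
  expect_equal(nrow(far$history), 1L)
  expect_equal(far$bandwidth, far$h_init)

  # fragments coincident with host windows can never separate
  expect_error(
    find_bandwidth(host, host[1:2, , drop = FALSE], h_init = 4),
    class = "islandshift_bandwidth_error"
  )
  err <- tryCatch(
    find_bandwidth(host, host[1:2, , drop = FALSE], h_init = 4),
    islandshift_bandwidth_error = function(cnd) cnd
  )
  expect_s3_class(err$history, "tbl_df")
  expect_false(any(err$history$separated))

  # closer fragments force decrements; verify grid maximality by re-scanning
  # the same grid exhaustively with an independent loop
  near <- rbind(rep(6, 4), rep(-6, 4))
  search <- find_bandwidth(host, near, h_init = 50, decay = 0.8)
  expect_gt(nrow(search$history), 1L)
  all_points <- rbind(host, near)
  art_idx <- nrow(host) + 1:2
  grid <- 50 * 0.8^(0:40)
  sep_grid <- vapply(grid, function(h) {
    is_separated(mean_shift(all_points, h)$labels, art_idx)
  }, logical(1))
  first_sep <- grid[which(sep_grid)[1]]
  expect_equal(search$bandwidth, first_sep)
  expect_false(any(sep_grid[grid > search$bandwidth]))

  # idempotence: re-clustering at the returned bandwidth still separates
  refit <- mean_shift(all_points, search$bandwidth)
  expect_true(is_separated(refit$labels, art_idx))

  # the recorded history decreases strictly
  expect_true(all(diff(search$history$h) < 0))
})

test_that("stronger implant divergence never shrinks the tuned bandwidth", {
  # as the artificial fragments move further from the host, separation is
  # achieved at the same or a larger kernel scale (ties allowed)
  set.seed(37)
  host <- matrix(rnorm(80, sd = 0.5), ncol = 4)
  offsets <- c(5, 8, 12, 20, 40)
  hs <- vapply(offsets, function(o) {
    frags <- rbind(rep(o, 4), rep(-o, 4))
    find_bandwidth(host, frags, h_init = 100, decay = 0.85)$bandwidth
  }, numeric(1))
  expect_true(all(diff(hs) >= 0))
})
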