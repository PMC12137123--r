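test_that("windowed SD matches hand values and brute-force recomputation", {
  flat <- elevation_grid(matrix(5, 20, 20))
  out <- local_sd(flat, 9)
  expect_true(all(out$heights[5:16, 5:16] == 0))

  # lone spike of 9 among zeros: window variance 72/8, sample SD 3
  h <- matrix(0, 5, 5)
  h[3, 3] <- 9
  spike <- local_sd(elevation_grid(h), 3)
  expect_equal(spike$heights[3, 3], 3)

  set.seed(42)
  for (k in 1:3) {
    h <- matrix(rnorm(900), 30, 30)
    h[sample(900, 25)] <- NA      # scatter some nodata
    g <- elevation_grid(h)
    mine <- local_sd(g, 9)$heights
    oracle <- brute_local_sd(h, 9)
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("micro-relief is translation invariant and scale equivariant", {
  set.seed(7)
  h <- matrix(rnorm(400), 20, 20)
  base <- local_sd(elevation_grid(h), 5)$heights
  shifted <- local_sd(elevation_grid(h + 123.456), 5)$heights
  scaled <- local_sd(elevation_grid(-3 * h), 5)$heights
  expect_equal(shifted, base, tolerance = 1e-9)
  expect_equal(scaled, 3 * base, tolerance = 1e-9)
})

test_that("margins and oversized windows are rejected or masked", {
  g <- elevation_grid(matrix(rnorm(100), 10, 10))
  out <- local_sd(g, 5)
  expect_true(all(is.na(out$heights[1:2, ])))
  expect_true(all(is.na(out$heights[, 9:10])))
  expect_error(local_sd(g, 11), "larger than the grid")
  expect_error(local_sd(g, 4), "odd")
})

test_that("subsampling partitions every valid cell exactly once", {
  set.seed(1)
  h <- matrix(runif(105), 7, 15)
  g <- elevation_grid(h, transect = "t1", location = "control")
  res <- subsample_maxima(g, n_bins = 20, seed = 9)
  expect_equal(nrow(res), 20)
  expect_equal(res$subsample, 1:20)
  # the global maximum always lands in some bin
  expect_equal(max(res$max_m), max(h))
  # determinism and seed sensitivity
  expect_identical(res, subsample_maxima(g, n_bins = 20, seed = 9))
  other <- subsample_maxima(g, n_bins = 20, seed = 10)
  expect_false(identical(res$max_m, other$max_m))
  expect_equal(max(other$max_m), max(h))
})

test_that("with exactly as many cells as bins each cell is its own bin", {
  h <- matrix(c(1:20, rep(NA, 5)), 5, 5)
  g <- elevation_grid(h)
  res <- subsample_maxima(g, n_bins = 20, seed = 3)
  expect_setequal(res$max_m, 1:20)
  expect_error(subsample_maxima(elevation_grid(matrix(1:12, 3, 4)), 20),
               "12 valid cells")
})

test_that("location comparison reproduces hand-ranked statistics", {
  same <- data.frame(location = rep(c("a", "b", "c"), each = 4),
                     max_m = rep(1:4, 3))
  cmp <- compare_locations(same)
  expect_equal(glance(cmp)$statistic, 0)
  expect_equal(glance(cmp)$p.value, 1)

  two <- data.frame(location = c("a", "a", "b", "b"), max_m = c(1, 2, 3, 4))
  expect_equal(glance(compare_locations(two))$statistic, 2.4)
  expect_equal(tidy(compare_locations(two))$p.value, 1 / 3)

  expect_error(compare_locations(data.frame(location = "a", max_m = 1)),
               "at least 2 locations")
})

test_that("sediment infill lowers the subsample maxima of a nodule field", {
  cfg0 <- small_synth_config()
  cfg1 <- small_synth_config(infill_depth_m = 0.01)
  lower <- vapply(1:5, function(s) {
    m0 <- subsample_maxima(local_sd(gen_dtm(cfg0, seed = s)), seed = s)
    m1 <- subsample_maxima(local_sd(gen_dtm(cfg1, seed = s)), seed = s)
    median(m1$max_m) < median(m0$max_m)
  }, logical(1))
  expect_true(all(lower))
})
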