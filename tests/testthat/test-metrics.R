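test_that("EVH counting matches a brute-force sort-and-count", {
  dims <- c(5, 5, 4)
  m <- full_mask(dims)
  for (seed in 1:5) {
    f <- random_field(dims, seed)
    th <- sort(c(0, sample(as.vector(f), 10), 150))
    ev <- compute_evh(f, m, th)
    brute <- sapply(th, function(t) mean(f >= t))
    expect_identical(ev$curve$fraction, brute)
  }
  # step-function and two-voxel examples
  u <- array(10, dim = dims)
  ev <- compute_evh(u, m, c(0, 5, 10, 10.5))
  expect_equal(ev$curve$fraction, c(1, 1, 1, 0))
  g2 <- voxel_grid(c(2, 1, 1))
  m2 <- roi_mask(array(TRUE, dim = c(2, 1, 1)), g2)
  ev2 <- compute_evh(array(c(1, 3), dim = c(2, 1, 1)), m2, c(0, 2, 4))
  expect_equal(ev2$curve$fraction, c(1, 0.5, 0))
})

test_that("EVH curves are monotone and start at one", {
  dims <- c(6, 6, 3)
  for (seed in 6:10) {
    ev <- compute_evh(random_field(dims, seed), full_mask(dims))
    expect_equal(ev$curve$fraction[1], 1)
    expect_true(all(diff(ev$curve$fraction) <= 0))
    expect_true(all(ev$curve$fraction >= 0))
  }
  expect_error(compute_evh(random_field(dims, 1), full_mask(dims),
                           c(0, 3, 2)), "ascending")
  empty <- roi_mask(array(FALSE, dim = dims), voxel_grid(dims))
  expect_error(compute_evh(random_field(dims, 1), empty), "empty")
})

test_that("the EVH area recovers the ROI mean (layer-cake identity)", {
  dims <- c(10, 10, 10)
  m <- full_mask(dims)
  for (seed in 1:4) {
    f <- random_field(dims, seed)
    auc <- evh_auc(compute_evh(f, m))
    expect_lt(abs(auc - mean(f)) / mean(f), 0.01)
    vals <- sort(unique(as.vector(f)))
    exact <- evh_auc(compute_evh(f, m, c(0, vals)), method = "exact")
    expect_equal(exact, mean(f), tolerance = 1e-12)
  }
  u <- array(10, dim = dims)
  expect_equal(evh_auc(compute_evh(u, m, c(0, 10)), "exact"), 10)
})

test_that("percentile intensities follow the at-least-x-percent rule", {
  dims <- c(5, 5, 4)
  m <- full_mask(dims)
  ladder <- array(1:100, dim = dims)
  expect_equal(intensity_percentile(ladder, m, 50), 51)
  expect_equal(intensity_percentile(ladder, m, 5), 96)
  expect_equal(intensity_percentile(ladder, m, 75), 26)
  u <- array(10, dim = dims)
  for (x in c(5, 50, 75)) expect_equal(intensity_percentile(u, m, x), 10)
  for (seed in 1:5) {
    f <- random_field(dims, seed)
    e75 <- intensity_percentile(f, m, 75)
    e50 <- intensity_percentile(f, m, 50)
    e5 <- intensity_percentile(f, m, 5)
    expect_true(e75 <= e50 && e50 <= e5)
  }
  expect_error(intensity_percentile(ladder, m, 0), "between")
})

test_that("volume-at-threshold and percentile are dual (Galois property)", {
  # exhaustive on small enumerated fields
  vals_grid <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
  m <- roi_mask(array(TRUE, dim = c(3, 1, 1)), voxel_grid(c(3, 1, 1)))
  for (r in seq_len(nrow(vals_grid))) {
    f <- array(as.numeric(vals_grid[r, ]), dim = c(3, 1, 1))
    for (x in c(1, 25, 33.4, 50, 66.7, 75, 99)) {
      t <- intensity_percentile(f, m, x)
      expect_gte(volume_at_threshold(f, m, t), x)
    }
  }
  # and on larger random fields, including ten-voxel ones
  m10 <- roi_mask(array(TRUE, dim = c(10, 1, 1)), voxel_grid(c(10, 1, 1)))
  for (seed in 1:20) {
    set.seed(seed)
    f <- array(sample(0:5, 10, TRUE), dim = c(10, 1, 1))
    for (x in seq(5, 95, by = 10)) {
      t <- intensity_percentile(f, m10, x)
      expect_gte(volume_at_threshold(f, m10, t), x)
    }
  }
  dims <- c(5, 5, 4)
  mf <- full_mask(dims)
  u <- array(10, dim = dims)
  expect_equal(volume_at_threshold(u, mf, 25), 0)
  expect_equal(volume_at_threshold(array(30, dim = dims), mf, 25), 100)
})

test_that("metrics are scale-equivariant", {
  dims <- c(6, 6, 4)
  m <- full_mask(dims)
  f <- random_field(dims, 42)
  c0 <- 3.7
  expect_equal(evh_auc(compute_evh(c0 * f, m)),
               c0 * evh_auc(compute_evh(f, m)), tolerance = 1e-9)
  for (x in c(5, 50, 75))
    expect_equal(intensity_percentile(c0 * f, m, x),
                 c0 * intensity_percentile(f, m, x), tolerance = 1e-12)
  for (t in c(10, 40, 80))
    expect_equal(volume_at_threshold(c0 * f, m, c0 * t),
                 volume_at_threshold(f, m, t))
})

test_that("pqm records satisfy their orderings and match brute force", {
  dims <- c(8, 8, 6)
  m <- full_mask(dims)
  e <- random_field(dims, 1)
  cd <- random_field(dims, 2) / 5
  rec <- pqm(e, cd, m, "TEST")
  expect_s3_class(rec, "pqm_record")
  expect_true(rec$e_75 <= rec$e_50 && rec$e_50 <= rec$e_5)
  expect_true(rec$v_e75 <= rec$v_e50 && rec$v_e50 <= rec$v_e25)
  # independent recomputation from raw voxels
  ev <- sort(as.vector(e), decreasing = TRUE)
  n <- length(ev)
  expect_equal(rec$v_e50, 100 * sum(ev >= 50) / n)
  expect_equal(rec$e_50, ev[ceiling(0.5 * n)])
  expect_equal(rec$e_5, ev[ceiling(0.05 * n)])
  expect_equal(rec$e_auc, mean(ev), tolerance = 0.01)
  cv <- sort(as.vector(cd), decreasing = TRUE)
  expect_equal(rec$v_cd10, 100 * sum(cv >= 10) / n)
  expect_equal(rec$cd_5, cv[ceiling(0.05 * n)])
  expect_equal(rec$cd_auc, mean(cv), tolerance = 0.01)
  # uniform-field worked example
  recu <- pqm(array(50, dim = dims), array(10, dim = dims), m, "UNIFORM")
  expect_equal(recu$v_e50, 100)
  expect_equal(recu$v_e75, 0)
  expect_equal(recu$e_auc, 50, tolerance = 0.01 * 50)
  expect_equal(recu$v_cd10, 100)
  expect_equal(recu$v_cd5, 100)
  expect_equal(recu$v_cd15, 0)
})
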