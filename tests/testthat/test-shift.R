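test_that("cluster slopes match the closed-form least squares", {
  ser <- series_fixture(c(10L, 11L, 12L), c(1.2, 1.0, 0.8))
  sl3 <- cluster_slopes(ser, min_size = 3L)
  expect_equal(sl3$slope, -0.2)
  expect_equal(sl3$pearson_R, -1)

  # clusters below four isoforms produce no record at the default gate
  expect_equal(nrow(cluster_slopes(ser)), 0L)

  # constant u: slope 0, R undefined, flagged out of gated analyses
  flat <- cluster_slopes(series_fixture(c(1L, 2L, 3L, 4L), rep(1, 4)))
  expect_equal(flat$slope, 0)
  expect_true(is.na(flat$pearson_R))
  expect_false(flat$ok)
})

test_that("slopes and R agree with an lm/cor oracle on random clusters", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    offs <- cumsum(c(sample.int(20, 1), sample.int(4, n - 1, TRUE)))
    u <- exp(rnorm(n, 0, 0.2))
    ser <- series_fixture(offs, u)
    sl <- cluster_slopes(ser)
    fit <- lm(u ~ offs)
    expect_equal(sl$slope, unname(coef(fit)[2]))
    expect_equal(sl$pearson_R, cor(offs, u))
  }
})

test_that("within-cluster medians use all pairs from gated clusters only", {
  # two genes: one clean monotone cluster, one zero-variance cluster (gated out)
  good <- series_fixture(c(10L, 11L, 12L, 13L), c(1.3, 1.2, 1.1, 1.0), "gA")
  flat <- series_fixture(c(10L, 11L, 12L, 13L), rep(1, 4), "gB")
  med <- within_cluster_spacing_medians(rbind(good, flat), R_threshold = 0.7,
                                        stat = "difference")
  expect_equal(med$spacing, c(1L, 2L, 3L))   # non-adjacent pairs included
  expect_equal(med$n_pairs, c(3L, 2L, 1L))   # only the gated cluster contributes
  expect_equal(med$median, c(-0.1, -0.2, -0.3))
})

test_that("between-cluster pairs use cluster-bounding isoforms", {
  ser <- series_fixture(c(10L, 12L, 40L, 44L), c(1.0, 0.9, 0.72, 0.7))
  med <- between_cluster_spacing_medians(ser, stat = "relative_ratio")
  expect_equal(med$spacing, 28L)            # 40 - 12
  expect_equal(med$median, 0.72 / 0.9)
  # single-cluster genes contribute nothing
  one <- series_fixture(c(10L, 12L), c(1, 1))
  expect_equal(nrow(between_cluster_spacing_medians(one)), 0L)
})

test_that("neighboring-pair differences are cluster-agnostic", {
  ser <- series_fixture(c(10L, 11L, 40L), c(1.0, 0.9, 0.85))
  med <- neighboring_pair_differences(ser)
  expect_equal(med$spacing, c(1L, 29L))
  expect_equal(med$median, c(-0.1, -0.05), tolerance = 1e-12)
  # identical genotypes: all differences are zero
  same <- series_fixture(c(1L, 3L, 9L), rep(1, 3))
  expect_true(all(neighboring_pair_differences(same)$median == 0))
})

test_that("recovered spacing medians follow the generator tilt", {
  sim <- make_genome(60, seed = 61)
  ser <- sim_series(sim, depth = 1e5, tilt = 0.9)
  med <- within_cluster_spacing_medians(ser, R_threshold = 0.7)
  d <- med$spacing[med$spacing <= 5]
  expect_true(all(abs(med$median[med$spacing <= 5] - 0.9^d) < 0.02))
  bet <- between_cluster_spacing_medians(ser)
  expect_true(all(abs(bet$median - 0.98) < 0.03))
})

test_that("inverting the tilt reflects ratios and negates slopes", {
  sim <- make_genome(60, seed = 62)
  fast <- sim_series(sim, depth = 1e5, tilt = 1 / 0.9, seed_wt = 3, seed_mut = 4)
  med_f <- within_cluster_spacing_medians(fast, R_threshold = 0.7)
  d <- med_f$spacing[med_f$spacing <= 5]
  expect_true(all(abs(med_f$median[med_f$spacing <= 5] - (1 / 0.9)^d) < 0.03))

  slow <- sim_series(sim, depth = 1e5, tilt = 0.9, seed_wt = 5, seed_mut = 6)
  sl_f <- cluster_slopes(fast); sl_s <- cluster_slopes(slow)
  expect_gt(median(sl_f$slope), 0)
  expect_lt(median(sl_s$slope), 0)

  # slower mutants give steeper trends, and negative medians at all spacings
  slower <- sim_series(sim, depth = 1e5, tilt = 0.8, seed_wt = 7, seed_mut = 8)
  expect_lt(median(cluster_slopes(slower)$slope), median(sl_s$slope))
  nd <- neighboring_pair_differences(slower)
  expect_true(all(nd$median < 0))
  # stronger tilt, larger magnitude at nucleotide (within-cluster) spacings;
  # at boundary spacings the difference scales with the (smaller) upstream u
  nd_slow <- neighboring_pair_differences(slow)
  common <- intersect(nd$spacing[nd$spacing <= 5], nd_slow$spacing)
  expect_true(all(nd$median[match(common, nd$spacing)] <
                  nd_slow$median[match(common, nd_slow$spacing)]))
})
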