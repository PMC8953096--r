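test_that("zero-SD tissue specs reproduce the reference means exactly", {
  tis <- tissue_spec("retrodiscal_tissue", "no_displacement", zero_sd = TRUE)
  p <- sample_voxel_params(tis, seed = 3)
  expect_equal(p$t2_short, 17.6)
  expect_equal(p$t2_long, 105.3)
  expect_equal(p$amp_short, 0.666)
  expect_equal(p$amp_long, 0.334)
})

test_that("voxel parameter draws are seeded and respect the constraints", {
  tis <- tissue_spec("disk", "no_displacement")
  a <- sample_voxel_params(tis, seed = 42)
  b <- sample_voxel_params(tis, seed = 42)
  expect_identical(a, b)

  set.seed(99)
  draws <- replicate(400, {
    p <- sample_voxel_params(tis)
    c(p$t2_short, p$t2_long, p$amp_short)
  })
  expect_true(all(draws[1, ] < draws[2, ]))      # ordering enforced
  expect_true(all(draws[1, ] > 1))               # truncation at 1 ms
  expect_true(all(draws[3, ] > 0.01 & draws[3, ] < 0.99))
})

test_that("Monte-Carlo mean of t2_short draws matches the configured mean", {
  tis <- tissue_spec("disk", "no_displacement") # mean 12.9, sd 2.1
  set.seed(123)
  n <- 1e4
  x <- replicate(n, sample_voxel_params(tis)$t2_short)
  se <- tis$sd_t2_short / sqrt(n)
  expect_lt(abs(mean(x) - 12.9), 3 * se)
})

test_that("degenerate tissue specs are rejected", {
  tis <- tissue_spec("disk", "no_displacement")
  tis$sd_t2_short <- -1
  expect_error(sample_voxel_params(tis), "non-negative")
  tis2 <- tissue_spec("disk", "no_displacement")
  tis2$mean_t2_short <- 200 # above the long mean
  expect_error(sample_voxel_params(tis2), "mean_t2_short < mean_t2_long")
  expect_error(tissue_spec("unknown_structure"), "unknown structure")
})

test_that("noiseless zero-SD phantoms carry the closed-form curve everywhere", {
  ph <- noiseless_phantom("masseter", nx = 3L, ny = 2L)
  expect_equal(dim(ph$volume), c(4L, 3L, 1L, 8L))
  expect_equal(sum(ph$label == 1L), 6L)

  ref <- tissue_curve("masseter")
  for (i in 1:3) for (j in 1:2) {
    expect_equal(ph$volume[i, j, 1, ], ref$signal, tolerance = 1e-12)
  }
  # background voxels are zero and unlabeled
  expect_true(all(ph$volume[4, , , ] == 0))
  expect_true(all(is.na(ph$truth$t2_short[ph$label == 0L])))
  expect_equal(ph$truth$t2_short[1, 1, 1], ref$tissue$mean_t2_short)
})

test_that("overlapping ROIs are rejected", {
  tis <- tissue_spec("disk", "no_displacement", zero_sd = TRUE)
  spec <- phantom_spec(
    dim = c(6L, 6L, 1L),
    rois = list(
      list(label = 1L, structure = "disk", tissue = tis,
           region = list(x = c(1, 3), y = c(1, 3), z = 1)),
      list(label = 2L, structure = "disk", tissue = tis,
           region = list(x = c(3, 5), y = c(3, 5), z = 1))
    )
  )
  expect_error(make_phantom(spec), "overlap")
})

test_that("gaussian noise at sigma zero is the identity and seeds reproduce", {
  ph <- noiseless_phantom("disk", nx = 3L, ny = 3L)
  expect_identical(add_noise(ph$volume, rep(0, 8), "gaussian", seed = 1),
                   ph$volume)
  n1 <- add_noise(ph$volume, rep(0.05, 8), "gaussian", seed = 7)
  n2 <- add_noise(ph$volume, rep(0.05, 8), "gaussian", seed = 7)
  expect_identical(n1, n2)
  expect_false(identical(n1, ph$volume))
  expect_error(add_noise(ph$volume, rep(0.05, 3), "gaussian"), "one sigma per echo")
})

test_that("rician noise on zero signal has the Rayleigh mean", {
  sigma <- 0.2
  zero <- array(0, dim = c(40, 40, 1, 2))
  noisy <- add_noise(zero, rep(sigma, 2), "rician", seed = 21)
  expect_true(all(noisy >= 0))
  # Rayleigh mean = sigma * sqrt(pi / 2); 3200 samples => SE ~ 0.1 * sigma / 56
  expect_equal(mean(noisy), sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("cohort generator produces the two-group design", {
  spec <- cohort_spec(seed = 5)
  coh <- make_cohort(spec)
  expect_equal(length(unique(coh$subject)), 50L)
  expect_equal(length(unique(coh$subject[coh$group == "displacement"])), 18L)
  expect_equal(length(unique(coh$subject[coh$group == "no_displacement"])), 32L)
  expect_equal(nrow(coh), 50L * 7L)
  expect_true(all(abs(coh$frac_short + coh$frac_long - 1) < 1e-12))

  coh2 <- make_cohort(cohort_spec(seed = 5))
  expect_identical(coh, coh2)
  expect_error(cohort_spec(n_displacement = 0), ">= 1")
})
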