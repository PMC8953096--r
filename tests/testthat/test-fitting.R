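tes8 <- default_echo_times()

test_that("inverse-variance weights are normalized to mean 1", {
  expect_equal(estimate_weights(rep(1, 8)), rep(1, 8))
  expect_equal(estimate_weights(c(1, 2)), c(1.6, 0.4))

  set.seed(31)
  bg <- matrix(rnorm(50 * 8, 0, rep(c(1, 2), each = 4)[col(matrix(0, 50, 8))]),
               nrow = 50)
  w <- estimate_weights(background = bg)
  expect_equal(mean(w), 1)
  expect_true(mean(w[1:4]) > mean(w[5:8])) # noisier echoes downweighted

  expect_error(estimate_weights(background = matrix(1, 50, 8)), "positive")
  expect_error(estimate_weights(background = matrix(rnorm(16), 2, 8)), ">= 20")
  expect_error(estimate_weights(c(1, 0, 1)), "positive")
})

test_that("weighted MSE follows its definition", {
  expect_equal(weighted_mse(c(1, 2), c(1, 2), c(1, 1)), 0)
  expect_equal(weighted_mse(c(1, 0), c(0, 1), c(1, 1)), 1)
  expect_equal(weighted_mse(c(2, 2), c(1, 1), c(2, 0)), 1)
  expect_error(weighted_mse(1:3, 1:2, 1:3), "equal length")
})

test_that("monoexponential fit recovers noiseless truth and flags zeros", {
  s <- mono_signal(mono_params(1, 50), tes8)
  f <- fit_mono(s, tes8)
  expect_false(f$degenerate)
  expect_equal(f$params$amp, 1, tolerance = 1e-3)
  expect_equal(f$params$t2, 50, tolerance = 1e-3)

  z <- fit_mono(rep(0, 8), tes8)
  expect_true(z$degenerate)

  # a genuinely biexponential curve cannot be fitted perfectly by one pool:
  # compare against the best mono fit found by brute force over a t2 lattice
  # with the closed-form optimal amplitude at each lattice point
  s2 <- biexp_signal(biexp_params(0.5, 0.5, 15, 150), tes8)
  f2 <- fit_mono(s2, tes8)
  lattice_best <- min(vapply(seq(1, 500, by = 0.5), function(t2) {
    e <- exp(-tes8 / t2)
    a <- sum(s2 * e) / sum(e * e)
    mean((s2 - a * e)^2)
  }, numeric(1)))
  expect_gt(f2$mse, 0)
  expect_lte(f2$mse, lattice_best + 1e-12)
})

test_that("biexponential fit recovers reference tissue truth within 0.1%", {
  for (structure in c("retrodiscal_tissue", "disk", "bone_marrow")) {
    ref <- tissue_curve(structure)
    f <- fit_biexp(ref$signal, tes8)
    expect_equal(f$params$t2_short, ref$params$t2_short, tolerance = 1e-3)
    expect_equal(f$params$t2_long, ref$params$t2_long, tolerance = 1e-3)
    fr <- fractions(f$params$amp_short, f$params$amp_long)
    expect_equal(fr[["frac_short"]],
                 ref$params$amp_short, tolerance = 1e-3)
    expect_lte(f$params$t2_short, f$params$t2_long)
  }
})

test_that("biexponential fit of a mono curve degenerates as expected", {
  s <- mono_signal(mono_params(1, 60), tes8)
  f <- fit_biexp(s, tes8)
  eps_amp <- 1e-6 * (f$params$amp_short + f$params$amp_long)
  collapsed <- abs(f$params$t2_long - f$params$t2_short) < 1 ||
    f$params$amp_short < eps_amp || f$params$amp_long < eps_amp
  expect_true(collapsed)
})

test_that("fits are deterministic and reject short echo trains", {
  set.seed(8)
  s <- biexp_signal(biexp_params(0.6, 0.4, 20, 100), tes8) + rnorm(8, 0, 0.01)
  f1 <- fit_biexp(s, tes8)
  f2 <- fit_biexp(s, tes8)
  expect_identical(f1, f2)
  expect_error(fit_biexp(s[1:4], tes8[1:4]), ">= 5 echoes")
  expect_error(fit_biexp(s[1:4], tes8), "match echo count")
})

test_that("reduced 3-parameter fit honors the amplitude-sum constraint", {
  ref <- tissue_curve("pterygoid_medialis")
  f <- fit_biexp(ref$signal, tes8, amp_total = 1)
  expect_equal(f$params$amp_short + f$params$amp_long, 1, tolerance = 1e-12)
  expect_equal(f$params$t2_short, ref$params$t2_short, tolerance = 1e-3)
  expect_equal(f$params$t2_long, ref$params$t2_long, tolerance = 1e-3)
})

test_that("biexp MSE nests below mono MSE on well-separated curves", {
  set.seed(23)
  for (i in 1:20) {
    t2s <- runif(1, 8, 40)
    t2l <- t2s * runif(1, 3, 8) # component ratio >= 3
    fs <- runif(1, 0.2, 0.8)
    s <- biexp_signal(biexp_params(fs, 1 - fs, t2s, t2l), tes8) +
      rnorm(8, 0, 0.005)
    bi <- fit_biexp(s, tes8)
    mono <- fit_mono(s, tes8)
    expect_lte(bi$mse, mono$mse + 1e-10)
  }
})

test_that("degeneracy classification is an order-free logical OR", {
  good_bi <- list(params = list(amp_short = 0.666, amp_long = 0.334,
                                t2_short = 17.6, t2_long = 105.3), mse = 1e-6)
  mono <- list(params = list(amp = 0.8, t2 = 50), mse = 1e-3)
  expect_equal(classify_voxel(good_bi, mono), "biexponential")

  close_t2 <- good_bi
  close_t2$params$t2_short <- 50.0
  close_t2$params$t2_long <- 50.5
  expect_equal(classify_voxel(close_t2, mono), "monoexponential")

  zero_amp <- good_bi
  zero_amp$params$amp_long <- 0
  expect_equal(classify_voxel(zero_amp, mono), "monoexponential")

  zero_t2 <- good_bi
  zero_t2$params$t2_short <- 0.001
  expect_equal(classify_voxel(zero_t2, mono), "monoexponential")

  mono_wins <- good_bi
  mono_wins$mse <- 2e-3 # above the mono MSE
  expect_equal(classify_voxel(mono_wins, mono), "monoexponential")

  expect_error(classify_voxel(NULL, mono), "both fits")

  # pure function: repeated calls and irrelevant extra fields do not matter
  expect_identical(classify_voxel(good_bi, mono), classify_voxel(good_bi, mono))
})
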