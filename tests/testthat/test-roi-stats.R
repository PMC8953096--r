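make_grid <- function(values, valid = rep(TRUE, length(values))) {
  n <- length(values)
  list(map = array(values, dim = c(n, 1, 1)),
       label = array(1L, dim = c(n, 1, 1)),
       validity = array(valid, dim = c(n, 1, 1)))
}

test_that("ROI summaries exclude degenerate voxels", {
  g <- make_grid(c(10, 20, 30))
  s <- roi_summary(g$map, g$label, g$validity)
  expect_equal(s$mean, 20)
  expect_equal(s$sd, 10)
  expect_equal(s$n_valid, 3L)

  g2 <- make_grid(c(10, 20, 30), valid = c(TRUE, TRUE, FALSE))
  s2 <- roi_summary(g2$map, g2$label, g2$validity)
  expect_equal(s2$mean, 15)
  expect_equal(s2$n_valid, 2L)

  g3 <- make_grid(c(10, 20, 30), valid = rep(FALSE, 3))
  s3 <- roi_summary(g3$map, g3$label, g3$validity)
  expect_true(s3$empty)
  expect_true(is.na(s3$mean))
})

test_that("repeat segmentations average their ROI means", {
  g <- make_grid(c(10, 20, 30, 40))
  labelA <- array(c(1L, 1L, 0L, 0L), dim = c(4, 1, 1)) # mean 15
  labelB <- array(c(0L, 0L, 1L, 1L), dim = c(4, 1, 1)) # mean 35
  s <- average_segmentations(g$map, labelA, labelB, g$validity)
  expect_equal(s$mean, 25)

  sAA <- average_segmentations(g$map, labelA, labelA, g$validity)
  sA <- roi_summary(g$map, labelA, g$validity)
  expect_equal(sAA$mean, sA$mean)
  expect_equal(sAA$sd, sA$sd)

  empty <- array(0L, dim = c(4, 1, 1))
  expect_warning(s1 <- average_segmentations(g$map, labelA, empty, g$validity),
                 "other alone")
  expect_equal(s1$mean, sA$mean)
})

test_that("pooled t-test reproduces the reference worked example", {
  # retrodiscal short T2 summaries: (22.6, 5.2, 18) vs (17.6, 3.0, 32)
  r <- pooled_t_test(22.6, 5.2, 18, 17.6, 3.0, 32)
  expect_equal(r$t, 4.3260217, tolerance = 1e-6)
  expect_equal(r$df, 48)
  expect_equal(r$p, 7.648057e-05, tolerance = 1e-5)
  expect_lt(r$p, 1e-4) # printed as "0.0001"

  ident <- pooled_t_test(5, 1, 10, 5, 1, 10)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)

  swap <- pooled_t_test(17.6, 3.0, 32, 22.6, 5.2, 18)
  expect_equal(swap$t, -r$t)
  expect_equal(swap$p, r$p)
})

test_that("pooled t-test agrees with t.test on raw samples", {
  set.seed(77)
  for (i in 1:10) {
    a <- rnorm(12, 5, 2)
    b <- rnorm(20, 6, 2.5)
    mine <- pooled_t_test(mean(a), sd(a), 12, mean(b), sd(b), 20)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    minew <- pooled_t_test(mean(a), sd(a), 12, mean(b), sd(b), 20, welch = TRUE)
    refw <- t.test(a, b)
    expect_equal(minew$p, refw$p.value, tolerance = 1e-10)
  }
})

test_that("pooled t-test is invariant to common rescaling and group order", {
  set.seed(13)
  for (i in 1:10) {
    m <- runif(2, 1, 30); s <- runif(2, 0.5, 5); k <- runif(1, 0.1, 10)
    p1 <- pooled_t_test(m[1], s[1], 18, m[2], s[2], 32)$p
    p2 <- pooled_t_test(k * m[1], k * s[1], 18, k * m[2], k * s[2], 32)$p
    p3 <- pooled_t_test(m[2], s[2], 32, m[1], s[1], 18)$p
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_equal(p1, p3, tolerance = 1e-12)
  }
  # zero-variance limit convention
  expect_equal(pooled_t_test(1, 0, 5, 1, 0, 5)$p, 1)
  expect_equal(pooled_t_test(1, 0, 5, 2, 0, 5)$p, 0)
})

test_that("Bonferroni threshold is family alpha over m", {
  expect_equal(bonferroni_alpha(0.05, 4), 0.0125)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.10, 5), 0.02)
  expect_error(bonferroni_alpha(0, 4), "family_alpha")
})

test_that("Shapiro-Wilk wrapper reproduces a published worked example", {
  # classic 11-point weight sample from the original W-test literature
  x <- c(148, 154, 158, 160, 161, 162, 166, 170, 182, 195, 236)
  r <- shapiro_wilk(x)
  expect_equal(round(r$W, 2), 0.79)
  expect_lt(r$p, 0.01)

  small <- shapiro_wilk(c(1.2, 3.4, 2.1))
  expect_true(r$W > 0 && r$W <= 1 && small$W > 0 && small$W <= 1)
  expect_error(shapiro_wilk(rep(1, 10)))
})

test_that("Pearson correlation matches hand-evaluable cases", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6, tolerance = 1e-12)
  # orthogonal by construction
  y <- c(1, -1, 1, -1, 1, -1)
  z <- c(1, 1, -1, -1, 1, 1) # cross products cancel
  expect_equal(pearson_r(y, z)$r, 0, tolerance = 1e-12)
})

test_that("Cohen's kappa matches the chance-corrected agreement formula", {
  r1 <- rep(c("yes", "no"), c(18, 32))
  expect_equal(cohens_kappa(r1, r1), 1)

  a <- rep(c(1, 0), 25)
  expect_equal(cohens_kappa(a, 1 - a), -1)

  # 2x2 table: 20 both-yes, 5 yes/no, 10 no/yes, 15 both-no
  x <- rep(c("y", "y", "n", "n"), c(20, 5, 10, 15))
  y <- rep(c("y", "n", "y", "n"), c(20, 5, 10, 15))
  k <- cohens_kappa(x, y)
  expect_equal(k, 0.4, tolerance = 1e-12)
  if (requireNamespace("e1071", quietly = TRUE)) {
    expect_equal(k, e1071::classAgreement(table(x, y))$kappa, tolerance = 1e-12)
  }
  expect_error(cohens_kappa(1:3, 1:4), "equal length")
})

test_that("intersection over union counts overlap correctly", {
  a <- c(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(intersection_over_union(a, a), 1)
  expect_equal(intersection_over_union(a, !a), 0)

  m1 <- c(rep(TRUE, 10), rep(FALSE, 8))
  m2 <- c(rep(FALSE, 4), rep(TRUE, 10), rep(FALSE, 4))
  expect_equal(intersection_over_union(m1, m2), 6 / 14)
  expect_equal(intersection_over_union(m2, m1), 6 / 14) # symmetric
  expect_error(intersection_over_union(logical(5), logical(5)), "undefined")
})
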