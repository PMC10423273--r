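test_that("curve comparison finds nothing under the null and everything under separation", {
  set.seed(51)
  A <- matrix(0.7 + rnorm(10 * 93, 0, 0.02), 10, 93)
  # exact copies: statistic is identically zero
  cmp0 <- hotelling_curve_test(A, A, n_perm = 100)
  expect_equal(nrow(cmp0$intervals), 0)
  expect_true(all(cmp0$statistic == 0))
  # well-separated constant curves: one interval covering the whole movement
  B <- matrix(0.9 + rnorm(10 * 93, 0, 0.005), 10, 93)
  C <- matrix(0.5 + rnorm(10 * 93, 0, 0.005), 10, 93)
  cmp1 <- hotelling_curve_test(B, C, n_perm = 200)
  expect_equal(nrow(cmp1$intervals), 1)
  expect_equal(unname(cmp1$intervals[1, ]), c(cmp1$pct[1], 100))
  expect_lt(cmp1$p_global, 0.01)
})

test_that("curve comparison is symmetric and seed-reproducible", {
  set.seed(52)
  A <- matrix(runif(5 * 20), 5, 20)
  B <- matrix(runif(5 * 20), 5, 20)
  set.seed(1); c1 <- hotelling_curve_test(A, B, n_perm = 100)
  set.seed(1); c2 <- hotelling_curve_test(B, A, n_perm = 100)
  expect_equal(c1$statistic, c2$statistic)
  set.seed(1); c3 <- hotelling_curve_test(A, B, n_perm = 100)
  expect_identical(c1$threshold, c3$threshold)
  expect_error(hotelling_curve_test(A, B[, 1:10]), "equal length")
})

test_that("chance-crossing times follow their defining cases", {
  expect_equal(chance_crossing_time(rep(1, 93), pct = (7:99) / 99 * 100),
               7 / 99 * 100)
  expect_true(is.na(chance_crossing_time(rep(0.5, 93))))  # strict inequality
  step <- c(rep(0.4, 30), rep(0.9, 70))
  expect_equal(chance_crossing_time(step), 30 / 99 * 100, tolerance = 1e-9)
})

test_that("chance crossing is monotone in the curve", {
  set.seed(53)
  for (i in 1:25) {
    a <- runif(50)
    b <- pmin(a + runif(50, 0, 0.3), 1)  # pointwise larger
    ca <- chance_crossing_time(a, level = 0.6, run_length = 3)
    cb <- chance_crossing_time(b, level = 0.6, run_length = 3)
    if (!is.na(ca)) {
      expect_false(is.na(cb))
      expect_lte(cb, ca)
    }
  }
})

test_that("confidence ellipses recover the covariance geometry", {
  set.seed(54)
  pts <- cbind(rnorm(10000), rnorm(10000))
  ell <- confidence_ellipse(pts)
  expect_equal(ell$eigenvalues, c(1, 1), tolerance = 0.05)
  expect_equal(sum(ell$eigenvalues), sum(diag(stats::cov(pts))),
               tolerance = 1e-9)
  # area uses the chi-square coverage scaling
  expect_equal(ell$area,
               pi * stats::qchisq(0.95, 2) *
                 sqrt(prod(ell$eigenvalues)), tolerance = 1e-9)
  # rotation invariance of eigenvalues and area
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ell_rot <- confidence_ellipse(pts %*% R)
  expect_equal(ell_rot$area, ell$area, tolerance = 1e-9)
  expect_equal(ell_rot$eigenvalues, ell$eigenvalues, tolerance = 1e-9)
  # collinear points degenerate cleanly
  line <- cbind(1:10, 2 * (1:10))
  ell_line <- confidence_ellipse(line)
  expect_true(ell_line$collinear)
  expect_equal(ell_line$area, 0, tolerance = 1e-9)
  expect_error(confidence_ellipse(cbind(1:2, 1:2)), "at least 3")
})

test_that("KS comparison of score distributions hits its boundary cases", {
  a <- c(0.8, 0.85, 0.9, 0.95, 0.99)
  expect_equal(compare_r2_distributions(a, a)$statistic, 0)
  b <- a - 10
  expect_equal(compare_r2_distributions(a, b)$statistic, 1)
  expect_error(compare_r2_distributions(a[1:3], a), "at least 5")
  # null calibration: same distribution rarely rejected
  set.seed(55)
  p_ok <- vapply(1:100, function(i) {
    compare_r2_distributions(rbeta(40, 5, 2), rbeta(40, 5, 2))$p_value > 0.05
  }, logical(1))
  expect_gte(mean(p_ok), 0.9)
})

test_that("Bonferroni-corrected t-tests use the stated thresholds", {
  set.seed(56)
  res <- corrected_two_sample_test(rnorm(12), rnorm(12), alpha = 0.05,
                                   n_comparisons = 4)
  expect_equal(res$threshold, 0.0125)
  # power: a 3-sd mean shift at n = 12 is detected essentially always
  hits <- vapply(1:20, function(i) {
    corrected_two_sample_test(rnorm(12), rnorm(12, 3), alpha = 0.05,
                              n_comparisons = 4)$significant
  }, logical(1))
  expect_gte(sum(hits), 19)
})
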