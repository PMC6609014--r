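test_that("OLS regression matches hand cases and the lm oracle", {
  r <- tr_regression(c(0, 1, 2), c(0, 1, 2))
  expect_equal(c(r$slope, r$intercept, r$r_squared), c(1, 0, 1))

  r2 <- tr_regression(c(0, 1, 2), c(1, 1, 4))
  expect_equal(r2$slope, 1.5)
  expect_equal(r2$intercept, 0.5)
  expect_equal(r2$r_squared, 0.75)

  r3 <- tr_regression(c(0, 1, 2, 5), -2 * c(0, 1, 2, 5) + 3)
  expect_equal(c(r3$slope, r3$intercept, r3$r_squared), c(-2, 3, 1))

  expect_error(tr_regression(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(tr_regression(1, 2), "at least 2")

  set.seed(42)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n, sd = runif(1, 0.1, 5))
    r <- tr_regression(x, y)
    fit <- lm(y ~ x)
    expect_equal(r$slope, unname(coef(fit)[2]), tolerance = 1e-12)
    expect_equal(r$intercept, unname(coef(fit)[1]), tolerance = 1e-12)
    expect_equal(r$r_squared, summary(fit)$r.squared, tolerance = 1e-12)
  }
})

test_that("cross-subject dispersion follows the stated convention", {
  m <- matrix(c(1, 2, 3), nrow = 1)
  expect_equal(cross_subject_se(m), 1 / 3)
  expect_equal(cross_subject_se(m, sqrt_n = TRUE), 1 / sqrt(3))
  expect_equal(cross_subject_se(matrix(5, 2, 4)), c(0, 0))
  expect_error(cross_subject_se(matrix(1, 3, 1)), "at least 2")
})

test_that("deviation maps: hand cases, symmetry and scale covariance", {
  n <- 50
  t1 <- matrix(rnorm(n * 3), n, 3)
  d0 <- deviation_map(t1, t1)
  expect_true(all(d0$mean_map == 0))
  expect_true(all(d0$percentiles == 0))

  # constant offset 0.5 with a group map of range 5
  g <- seq(0, 5, length.out = n)
  d1 <- deviation_map(matrix(g, n, 2), matrix(g + 0.5, n, 2), group_map = g)
  expect_equal(unname(d1$mean_map), rep(0.1, n))
  expect_equal(unname(d1$percentiles), rep(0.1, 4))

  set.seed(17)
  a <- matrix(rnorm(n * 4, 10), n, 4); b <- matrix(rnorm(n * 4, 10), n, 4)
  dab <- deviation_map(a, b); dba <- deviation_map(b, a)
  expect_equal(dab$mean_map, dba$mean_map)
  dsc <- deviation_map(3 * a, 3 * b)
  expect_equal(dsc$mean_map, dab$mean_map, tolerance = 1e-12)

  expect_error(deviation_map(a, b, group_map = rep(1, n)), "zero group range")

  # percentile convention: linear interpolation between order statistics
  x <- dab$mean_map
  ps <- c(0.25, 0.5, 0.75, 0.98)
  manual <- vapply(ps, function(p) {
    xs <- sort(x); h <- (length(xs) - 1) * p
    lo <- floor(h) + 1
    xs[lo] + (h - floor(h)) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }, numeric(1))
  expect_equal(unname(dab$percentiles), manual, tolerance = 1e-12)
})

test_that("pooled t-test and Cohen's d match hand formulas and t.test", {
  e <- region_pair_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(e$cohens_d, -1)
  expect_equal(e$dof, 4)
  expect_equal(e$t_statistic, -sqrt(1.5), tolerance = 1e-12)

  same <- region_pair_test(c(1, 2, 3), c(3, 1, 2))
  expect_equal(same$cohens_d, 0)
  expect_identical(same$size_class, "small")

  expect_identical(effect_size_class(1.17), "large")
  expect_identical(effect_size_class(c(0.3, 0.5, -0.9, 1.5, 2.4)),
                   c("small", "medium", "large", "very large", "huge"))

  expect_error(region_pair_test(c(1, 1), c(1, 1)), "zero pooled variance")

  set.seed(5)
  for (i in 1:100) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    e <- region_pair_test(a, b)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(e$t_statistic, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(e$p_value, tt$p.value, tolerance = 1e-12)
    expect_equal(e$dof, unname(tt$parameter))
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    expect_equal(e$cohens_d, (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  }
})

test_that("left-right regression has the documented axis order", {
  v <- c(0.6, 0.7, 0.8, 1.0, 1.2)
  r <- lr_correlation(v, v)
  expect_equal(c(r$slope, r$intercept, r$r_squared), c(1, 0, 1))
  # right shifted by +c: left (y) = right (x) - c
  rs <- lr_correlation(v, v + 0.3)
  expect_equal(rs$slope, 1)
  expect_equal(rs$intercept, -0.3)

  # independent values: R^2 small, consistent with the permutation null
  set.seed(33)
  obs <- lr_correlation(rnorm(12), rnorm(12))$r_squared
  perm <- replicate(400, {
    x <- rnorm(12); y <- rnorm(12)
    tr_regression(x, y)$r_squared
  })
  expect_lt(obs, quantile(perm, 0.999))
  expect_equal(mean(perm), 1 / 11, tolerance = 0.35) # E[R^2] = 1/(n-1)
})

test_that("asymmetry-vs-B1 correlation behaves at the extremes", {
  set.seed(2)
  b1l <- runif(200, 0.9, 1.1); b1r <- runif(200, 0.9, 1.1)
  d <- b1l - b1r
  expect_equal(asymmetry_vs_b1(d, rep(0, 200), b1l, b1r), 1)
  expect_equal(asymmetry_vs_b1(-d, rep(0, 200), b1l, b1r), -1)
  expect_error(asymmetry_vs_b1(rep(1, 5), rep(0, 5), runif(5), runif(5)),
               "constant")

  n <- 2e4
  ml <- rnorm(n); mr <- rnorm(n)
  bl <- rnorm(n); br <- rnorm(n)
  expect_lt(abs(asymmetry_vs_b1(ml, mr, bl, br)), 0.1)
  expect_equal(asymmetry_vs_b1(ml, mr, bl, br), cor(ml - mr, bl - br),
               tolerance = 1e-12)
})
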