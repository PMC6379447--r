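test_that("paired_sample validates its contract", {
  expect_error(paired_sample(1:3, 1:2), "equal length")
  expect_error(paired_sample(1, 2), "n >= 2")
  expect_error(paired_sample(c(1, NA), c(1, 2)), "missing")
  s <- paired_sample(c(1, 2), c(3, 4), c("a", "b"))
  expect_s3_class(s, "paired_sample")
})

test_that("paired t-test matches the hand formula and the reference", {
  s <- paired_sample(c(1, 2, 3), c(2, 4, 6))
  res <- paired_t_test(s)
  # d = (-1,-2,-3): t = -2 / (1/sqrt(3)) = -2*sqrt(3)
  expect_equal(res$statistic, -2 * sqrt(3), tolerance = 1e-12)
  expect_identical(res$df, 2L)
  ref <- stats::t.test(s$x, s$y, paired = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # antisymmetry in the statistic, same p
  rev <- paired_t_test(paired_sample(s$y, s$x))
  expect_equal(rev$statistic, -res$statistic)
  expect_equal(rev$p_value, res$p_value)
})

test_that("zero-variance differences are degenerate", {
  expect_error(paired_t_test(paired_sample(c(1, 2, 3), c(1, 2, 3))),
               "zero variance")
  expect_error(paired_t_test(paired_sample(c(10, 20), c(9, 19))),
               "zero variance")
})

test_that("pearson_r covers the exact anchors", {
  x <- 1:5
  expect_equal(pearson_r(paired_sample(x, 2 * x + 1))$statistic, 1)
  expect_equal(pearson_r(paired_sample(1:4, 4:1))$statistic, -1)
  expect_equal(pearson_r(paired_sample(x, 2 * x + 1))$p_value, 0)
  # hand evaluation: sum(dx*dy) = 10, sum(dx^2) = 10, sum(dy^2) = 14.8
  res <- pearson_r(paired_sample(1:5, c(2, 1, 4, 3, 6)))
  expect_equal(res$statistic, 10 / sqrt(10 * 14.8), tolerance = 1e-12)
  expect_identical(res$df, 3L)
  expect_error(pearson_r(paired_sample(1:2, 2:3)), "n >= 3")
  expect_error(pearson_r(paired_sample(c(1, 1, 1), 1:3)), "constant")
})

test_that("pearson_r is affine-invariant and sign-flips under negation", {
  set.seed(20)
  x <- stats::rnorm(15); y <- stats::rnorm(15)
  r0 <- pearson_r(paired_sample(x, y))$statistic
  expect_equal(pearson_r(paired_sample(3 * x + 7, 0.5 * y - 2))$statistic, r0,
               tolerance = 1e-12)
  expect_equal(pearson_r(paired_sample(-2 * x, y))$statistic, -r0,
               tolerance = 1e-12)
})

test_that("linear_regression matches closed-form OLS", {
  fit <- linear_regression(paired_sample(c(0, 1, 2), c(1, 3, 4)))
  expect_equal(fit$slope, 1.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 7 / 6, tolerance = 1e-12)
  exact <- linear_regression(paired_sample(1:5, 2 * (1:5) + 1))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)
  flat <- linear_regression(paired_sample(1:4, rep(3, 4)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(linear_regression(paired_sample(rep(2, 3), 1:3)),
               "constant x")
})

test_that("r_squared equals squared Pearson r for simple OLS", {
  set.seed(21)
  for (i in 1:10) {
    x <- stats::rnorm(12); y <- 0.8 * x + stats::rnorm(12)
    s <- paired_sample(x, y)
    expect_equal(linear_regression(s)$r_squared,
                 pearson_r(s)$statistic^2, tolerance = 1e-12)
  }
})

test_that("KS statistic is a sup-difference in [0,1] with sane behaviour", {
  set.seed(22)
  res <- ks_normality(stats::rnorm(30))
  expect_gte(res$statistic, 0)
  expect_lte(res$statistic, 1)
  # normal quantiles at plotting positions fit their own normal well
  q <- stats::qnorm((1:20) / 21)
  expect_lt(ks_normality(q)$statistic, 0.1)
  # power, with a brute-force ECDF cross-check of D. Because mu and
  # sigma are fitted from the sample, a uniform sample only clears the
  # parameter-fitted (Lilliefors) 5% critical value ~0.886/sqrt(n);
  # a strongly bimodal sample clears even the fully-specified 1.36/sqrt(n).
  for (s in 1:5) {
    set.seed(300 + s)
    u <- stats::runif(200)
    res <- ks_normality(u)
    ref_d <- stats::ks.test(u, "pnorm", mean(u), stats::sd(u))$statistic
    expect_equal(unname(res$statistic), unname(ref_d), tolerance = 1e-12)
    expect_gt(res$statistic, 0.886 / sqrt(200))
    bi <- c(stats::rnorm(100, -2, 0.5), stats::rnorm(100, 2, 0.5))
    expect_gt(ks_normality(bi)$statistic, 1.36 / sqrt(200))
  }
  expect_error(ks_normality(rep(1, 5)), "constant")
  expect_error(ks_normality(1:2), "n >= 3")
})

test_that("variance F-test orders the ratio above one and matches var.test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(variance_ratio_test(x, x)$statistic, 1)
  # constructed sds 2 and 1: F = 4 exactly
  res <- variance_ratio_test(c(-2, 0, 2), c(-1, 0, 1))
  expect_equal(res$statistic, 4)
  expect_identical(res$df, c(2L, 2L))
  # F >= 1 regardless of argument order, p matches var.test
  set.seed(23)
  for (i in 1:10) {
    u <- stats::rnorm(8); v <- stats::rnorm(6, sd = 2)
    res <- variance_ratio_test(u, v)
    expect_gte(res$statistic, 1)
    expect_equal(res$p_value, stats::var.test(u, v)$p.value, tolerance = 1e-12)
  }
  expect_error(variance_ratio_test(c(1, 1), c(1, 2)), "zero variance")
})

test_that("all five tests agree with the reference implementations on random samples", {
  set.seed(24)
  for (i in 1:40) {
    n <- sample(4:25, 1)
    x <- stats::rnorm(n, mean = 30, sd = stats::runif(1, 0.5, 10))
    y <- x + stats::rnorm(n, sd = stats::runif(1, 0.5, 5))
    s <- paired_sample(x, y)

    ref_t <- stats::t.test(x, y, paired = TRUE)
    mine <- paired_t_test(s)
    expect_equal(mine$statistic, unname(ref_t$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref_t$p.value, tolerance = 1e-6)

    ref_r <- stats::cor.test(x, y)
    mine_r <- pearson_r(s)
    expect_equal(mine_r$statistic, unname(ref_r$estimate), tolerance = 1e-9)
    expect_equal(mine_r$p_value, ref_r$p.value, tolerance = 1e-6)

    ref_lm <- stats::lm(y ~ x)
    fit <- linear_regression(s)
    expect_equal(fit$slope, unname(stats::coef(ref_lm)[2]), tolerance = 1e-9)
    expect_equal(fit$intercept, unname(stats::coef(ref_lm)[1]),
                 tolerance = 1e-9)
    expect_equal(fit$r_squared, summary(ref_lm)$r.squared, tolerance = 1e-9)

    ref_ks <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x), exact = FALSE))
    mine_ks <- ks_normality(x)
    expect_equal(mine_ks$statistic, unname(ref_ks$statistic),
                 tolerance = 1e-9)
    expect_equal(mine_ks$p_value, ref_ks$p.value, tolerance = 1e-6)

    ref_f <- stats::var.test(x, y)
    mine_f <- variance_ratio_test(x, y)
    expect_equal(mine_f$statistic,
                 max(unname(ref_f$statistic), 1 / unname(ref_f$statistic)),
                 tolerance = 1e-9)
    expect_equal(mine_f$p_value, ref_f$p.value, tolerance = 1e-6)
  }
})

test_that("compare_methods bundles the design and handles exact agreement", {
  # positive control: constant shift with tiny noise is significant
  set.seed(25)
  x <- stats::runif(11, 10, 50)
  y <- x + 5 + stats::rnorm(11, sd = 0.1)
  rep <- compare_methods(paired_sample(x, y))
  expect_lt(rep$paired_t$p_value, 0.05)
  expect_identical(rep$paired_t$df, 10L)   # df = n - 1 for n = 11
  expect_gt(rep$correlation$statistic, 0.99)
  # exact agreement: note instead of a failure
  rep2 <- compare_methods(paired_sample(x, x))
  expect_null(rep2$paired_t)
  expect_match(rep2$note, "identical")
  expect_equal(rep2$correlation$statistic, 1)
  expect_output(print(rep), "paired t-test")
  expect_output(print(rep2), "note")
})
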