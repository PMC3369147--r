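test_that("pooled t-test matches hand-computed values", {
  t0 <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$t, 0)
  expect_equal(t0$p_two_sided, 1)

  t1 <- student_t(c(1, 2, 3), c(4, 5, 6))
  ## pooled SD 1, SE = sqrt(2/3): t = -3 / sqrt(2/3)
  expect_equal(t1$t, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(t1$df, 4)
  expect_equal(t1$p_two_sided, 2 * pt(-abs(t1$t), 4), tolerance = 1e-12)

  ## a 10-SD location shift at the study group sizes is overwhelming
  set.seed(8)
  a <- rnorm(18); b <- rnorm(16) + 10
  expect_lt(student_t(a, b)$p_two_sided, 1e-3)
})

test_that("t statistics are invariant under common location/scale changes", {
  set.seed(9)
  a <- rnorm(12); b <- rnorm(15, 0.8)
  t1 <- student_t(a, b)
  t2 <- student_t(3 + 2 * a, 3 + 2 * b)
  expect_equal(t1$t, t2$t, tolerance = 1e-9)
  expect_equal(t1$p_two_sided, t2$p_two_sided, tolerance = 1e-9)
})

test_that("ICC(2,1) equals 1 for identical raters and matches the ANOVA oracle", {
  set.seed(10)
  x <- rnorm(12)
  r1 <- icc(cbind(x, x))
  expect_equal(r1$icc, 1, tolerance = 1e-12)
  expect_equal(r1$category, "almost perfect")

  for (i in 1:10) {
    mat <- matrix(rnorm(20, sd = runif(1, 0.5, 3)), 10, 2) +
      rnorm(10)  # shared subject effect
    expect_equal(icc(mat)$icc, aov_icc_oracle(mat), tolerance = 1e-10)
  }
  ## three raters too
  mat3 <- matrix(rnorm(30), 10, 3) + rnorm(10)
  expect_equal(icc(mat3)$icc, aov_icc_oracle(mat3), tolerance = 1e-10)
})

test_that("independent raters give near-zero ICC and noise degrades agreement", {
  set.seed(12)
  r <- icc(cbind(rnorm(200), rnorm(200)))
  expect_lt(abs(r$icc), 0.15)
  expect_equal(r$category, "slight")

  ## adding noise of growing SD to one column decreases the ICC
  set.seed(13)
  x <- rnorm(60)
  vals <- sapply(c(0.1, 0.5, 1.5, 4), function(s) {
    set.seed(99)
    icc(cbind(x, x + rnorm(60, 0, s)))$icc
  })
  expect_true(all(diff(vals) < 0))
})

test_that("constant ratings are flagged as undefined", {
  expect_error(icc(matrix(5, 10, 2)), "constant")
})

test_that("the agreement bands follow the published interpretation", {
  expect_equal(interpret_icc(0.85), "almost perfect")
  expect_equal(interpret_icc(0.52), "moderate")
  expect_equal(interpret_icc(0.15), "slight")
  expect_equal(interpret_icc(0.20), "slight")
  expect_equal(interpret_icc(0.40), "fair")
  expect_equal(interpret_icc(0.60), "moderate")
  expect_equal(interpret_icc(0.80), "substantial")
  expect_equal(interpret_icc(0.81), "almost perfect")
  expect_equal(interpret_icc(-0.3), "slight")
  expect_error(interpret_icc(1.2), "exceed")
})

test_that("simple regression matches closed forms exactly", {
  f <- simple_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$pearson_r, 1, tolerance = 1e-12)

  set.seed(14)
  x <- 1:20
  y <- -x + rnorm(20, 0, 1e-8)
  f2 <- simple_regression(x, y)
  expect_equal(f2$slope, -1, tolerance = 1e-6)
  expect_equal(f2$pearson_r, -1, tolerance = 1e-6)

  ## closed-form oracle at the study size
  set.seed(15)
  x <- rnorm(34); y <- 0.7 * x + rnorm(34)
  f3 <- simple_regression(x, y)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  beta <- sxy / sxx
  r <- sxy / sqrt(sxx * syy)
  tv <- r * sqrt(32 / (1 - r^2))
  expect_equal(f3$slope, beta, tolerance = 1e-10)
  expect_equal(f3$pearson_r, r, tolerance = 1e-10)
  expect_equal(f3$p, 2 * pt(-abs(tv), 32), tolerance = 1e-10)
  expect_equal(sign(f3$slope), sign(f3$pearson_r))
})

test_that("regression is scale-equivariant and rejects constant x", {
  set.seed(16)
  x <- rnorm(15); y <- rnorm(15)
  f1 <- simple_regression(x, y)
  f2 <- simple_regression(10 * x, y)
  expect_equal(f2$slope, f1$slope / 10, tolerance = 1e-12)
  expect_equal(f2$pearson_r, f1$pearson_r, tolerance = 1e-12)
  expect_equal(f2$p, f1$p, tolerance = 1e-12)
  expect_error(simple_regression(rep(1, 5), rnorm(5)), "constant")
})

test_that("tidy and glance methods return one-row summaries", {
  tt <- student_t(rnorm(10), rnorm(10))
  expect_s3_class(tidy(tt), "tbl_df")
  r <- icc(cbind(rnorm(10), rnorm(10)))
  expect_named(glance(r), c("icc", "category", "n_subjects", "n_raters"))
  f <- simple_regression(rnorm(10), rnorm(10))
  expect_equal(nrow(glance(f)), 1)
})
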