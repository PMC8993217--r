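test_that("LOSO regression is exact for a perfect linear relationship", {
  set.seed(51)
  score <- matrix(rnorm(5 * 16), 5, 16)
  fit <- loso_regression(score, 0.1 + 2 * score)
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(fit$coefficients[, "slope"]), rep(2, 5))
  expect_equal(unname(fit$coefficients[, "intercept"]), rep(0.1, 5))
})

test_that("degenerate LOSO inputs raise errors", {
  set.seed(52)
  score <- matrix(rnorm(4 * 16), 4, 16)
  expect_error(loso_regression(score, matrix(0.5, 4, 16)), "constant")
  expect_error(loso_regression(matrix(1, 4, 16), matrix(rnorm(64), 4, 16)),
               "zero variance")
  expect_error(loso_regression(score[1:2, ], matrix(rnorm(32), 2, 16)),
               "3 subjects")
  expect_error(loso_regression(score, matrix(rnorm(32), 2, 16)), "shape")
})

test_that("held-out behavior never leaks into the fold coefficients", {
  set.seed(53)
  score <- matrix(rnorm(5 * 16), 5, 16)
  behavior <- 0.5 + 0.3 * score + matrix(rnorm(80, sd = 0.1), 5, 16)
  f1 <- loso_regression(score, behavior)
  behavior2 <- behavior
  behavior2[2, ] <- behavior2[2, ] + 10
  f2 <- loso_regression(score, behavior2)
  expect_equal(f1$coefficients[2, ], f2$coefficients[2, ])
})

test_that("unrelated predictors give non-positive R-squared on average", {
  set.seed(54)
  r2 <- replicate(100, {
    loso_regression(matrix(rnorm(6 * 16), 6, 16),
                    matrix(runif(6 * 16), 6, 16))$r_squared
  })
  expect_lt(mean(r2), 0.02)
})

test_that("LOSO permutation p detects coupling and respects its seed", {
  set.seed(55)
  score <- matrix(rnorm(6 * 16), 6, 16)
  behavior <- 0.4 + 0.5 * score + matrix(rnorm(96, sd = 0.05), 6, 16)
  out <- loso_permutation_p(score, behavior, n_perm = 99, seed = 3)
  expect_equal(out$p, 0)  # reported as < 1/n_perm
  expect_gt(out$z, 3)
  out2 <- loso_permutation_p(score, behavior, n_perm = 99, seed = 3)
  expect_identical(out$null, out2$null)
  expect_error(loso_permutation_p(score, behavior, n_perm = 0), "n_perm")
})

test_that("nested F matches the explicit SSE algebra of lm/anova", {
  y <- matrix(c(0, 1, 2.2, 3, 4.1, 5), 1)
  x1 <- matrix(c(0, 1, 2, 3, 4, 5), 1)
  x2 <- matrix(c(0, 0, 1, 1, 2, 2), 1)
  # independent oracle: R's anova on the two pooled fits
  f_r <- lm(as.vector(y) ~ as.vector(x1))
  f_f <- lm(as.vector(y) ~ as.vector(x1) + as.vector(x2))
  want <- anova(f_r, f_f)$F[2]
  got <- nested_f(x1, x2, y, n_perm = 5, seed = 1)
  expect_equal(got$F, want, tolerance = 1e-10)
})

test_that("nested F is zero when the added term adds nothing", {
  x1 <- matrix(seq(0, 5, length.out = 12), 2)
  y <- 1 + 2 * x1
  x2 <- matrix(rep(c(0, 1), 6), 2)
  expect_equal(nested_f(x1, x2, y, n_perm = 5, seed = 1)$F, 0)
  expect_error(nested_f(x1, x1 * 1.0000001, y, n_perm = 2), "collinear")
})

test_that("nested F detects planted added value of schema scores", {
  set.seed(56)
  story <- matrix(rnorm(10 * 16), 10, 16)
  schema <- matrix(rnorm(10 * 16), 10, 16)
  y <- 0.2 + 0.3 * story + 0.3 * schema + matrix(rnorm(160, sd = 0.1), 10, 16)
  out <- nested_f(story, schema, y, n_perm = 99, seed = 2)
  expect_gt(out$F, 10)
  expect_lt(out$p, 0.05)
})

test_that("coefficient contrasts behave at the degenerate extremes", {
  set.seed(57)
  coefs <- rnorm(20)
  same <- coefficient_contrast(coefs, coefs, n_perm = 99, seed = 1)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  shift <- coefficient_contrast(coefs + 1, coefs, n_perm = 199, seed = 1)
  expect_equal(shift$delta, 1)
  expect_lt(shift$p, 0.05)
  expect_error(coefficient_contrast(coefs, coefs[1:3]), "mismatched")
})

test_that("map-to-target regression flags the planted unit", {
  set.seed(58)
  target <- matrix(rnorm(8 * 16), 8, 16)
  preds <- list(target + matrix(rnorm(128, sd = 0.2), 8, 16),
                matrix(rnorm(128), 8, 16),
                matrix(rnorm(128), 8, 16))
  out <- predict_target_from_maps(target, preds, n_perm = 199, seed = 4)
  expect_equal(which.min(out$q), 1)
  expect_lt(out$q[1], 0.05)
  single <- predict_target_from_maps(target, preds[1], n_perm = 99, seed = 4)
  expect_equal(single$q, single$p)  # BH with m = 1
})
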