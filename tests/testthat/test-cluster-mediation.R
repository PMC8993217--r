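test_that("feature stacking masks, drops and reports missing vertices", {
  maps <- list(a = c(1, 2, 3, 4, 5), b = c(5, 4, NA, 2, 1),
               c = c(0, 1, 0, 1, 0))
  expect_message(mat <- stack_features(maps, mask = c(TRUE, TRUE, TRUE,
                                                      TRUE, FALSE)),
                 "dropped")
  expect_equal(dim(mat), c(3, 3))
  expect_equal(attr(mat, "vertices"), c(1, 2, 4))
  expect_error(stack_features(maps, mask = rep(FALSE, 5)), "empty mask")
  expect_warning(stack_features(list(m1 = 1:50 / 10, m2 = 1:50 / 10),
                                mask = rep(TRUE, 50)), "rank")
})

test_that("silhouette selection recovers the planted number of blobs", {
  set.seed(61)
  blob <- function(center, n) {
    sweep(matrix(rnorm(n * 8, sd = 0.1), n, 8), 2, center, "+")
  }
  two <- rbind(blob(rep(0, 8), 40), blob(rep(5, 8), 40))
  sel2 <- kmeans_select(two, k_candidates = 2:7, seed = 1)
  expect_equal(sel2$k, 2)
  expect_gt(sel2$silhouette["2"], 0.8)
  truth2 <- rep(1:2, each = 40)
  expect_equal(adjusted_rand(sel2$labels, truth2), 1)

  three <- rbind(blob(rep(0, 8), 30), blob(rep(5, 8), 30),
                 blob(c(rep(-5, 4), rep(5, 4)), 30))
  sel3 <- kmeans_select(three, k_candidates = 2:4, seed = 1)
  expect_equal(sel3$k, 3)
  expect_equal(adjusted_rand(sel3$labels, rep(1:3, each = 30)), 1)

  # labels are stable across seeds up to relabeling
  selb <- kmeans_select(two, k_candidates = 2:7, seed = 99)
  expect_equal(adjusted_rand(sel2$labels, selb$labels), 1)
})

test_that("degenerate clustering inputs are refused", {
  flat <- matrix(1, 20, 8)
  expect_error(kmeans_select(flat, 2:3, seed = 1), "degenerate")
  expect_error(kmeans_select(matrix(rnorm(24), 3, 8), k_candidates = 2:5),
               "fewer samples")
})

test_that("full mediation recovers the exact algebraic identity", {
  set.seed(71)
  x <- rnorm(50)
  fit <- mediate(x, x, x, n_boot = 50, seed = 1)
  expect_equal(fit$a, 1)
  expect_equal(fit$b, 1)
  expect_equal(fit$cprime, 0)
  expect_equal(fit$c, 1)
  expect_equal(fit$indirect, 1)
})

test_that("c = c' + a*b holds exactly for standardized OLS fits", {
  set.seed(72)
  for (rep in 1:20) {
    x <- rnorm(40); m <- 0.5 * x + rnorm(40); y <- 0.3 * m + 0.2 * x + rnorm(40)
    fit <- mediate(x, m, y, n_boot = 20, seed = rep)
    expect_lt(abs(fit$c - (fit$cprime + fit$a * fit$b)), 1e-10)
    # cross-check the paths against lm on standardized variables
    zs <- function(v) (v - mean(v)) / sd(v)
    expect_equal(fit$a, unname(coef(lm(zs(m) ~ zs(x)))[2]), tolerance = 1e-10)
    cf <- coef(lm(zs(y) ~ zs(m) + zs(x)))
    expect_equal(fit$b, unname(cf[2]), tolerance = 1e-10)
    expect_equal(fit$cprime, unname(cf[3]), tolerance = 1e-10)
  }
})

test_that("planted mediation is recovered with a CI excluding zero", {
  set.seed(73)
  n <- 480
  x <- rnorm(n)
  m <- 0.6 * x + rnorm(n, sd = 0.3)
  y <- 0.5 * m + rnorm(n, sd = 0.3)
  fit <- mediate(x, m, y, n_boot = 1000, seed = 2)
  a_std <- 0.6 / sqrt(0.6^2 + 0.3^2)
  b_partial <- fit$a * fit$b  # standardized indirect effect
  expect_gt(fit$ci[1], 0)
  expect_gt(fit$indirect, 0.3)  # strong planted paths
  expect_equal(fit$indirect, b_partial)
})

test_that("mediation inputs are validated", {
  expect_error(mediate(rnorm(5), rnorm(5), rnorm(5)), "at least 10")
  expect_error(mediate(rep(1, 20), rnorm(20), rnorm(20), n_boot = 10),
               "zero variance in x")
  expect_error(mediate(rnorm(4), rnorm(5), rnorm(5)), "equal length")
})

test_that("path permutation tests calibrate around z = 0 under the null", {
  set.seed(74)
  x <- rnorm(200); m <- rnorm(200); y <- rnorm(200)
  out <- path_p("a", x, m, y, n_perm = 500, seed = 1)
  expect_lt(abs(out$z), 3)
  expect_true(out$p > 0.001 && out$p < 0.999)
  strong <- path_p("a", x, 0.9 * x + rnorm(200, sd = 0.2), y,
                   n_perm = 500, seed = 1)
  expect_lt(strong$p, 0.001)
  expect_error(path_p("a", x, m, y, n_perm = 1), "n_perm")
})

test_that("the reverse-direction variant swaps the causal roles", {
  set.seed(75)
  x <- rnorm(100); m <- 0.7 * x + rnorm(100, sd = 0.3)
  y <- 0.5 * m + rnorm(100, sd = 0.3)
  fwd <- mediate(x, m, y, n_boot = 100, seed = 1)
  rev <- mediate(x, m, y, n_boot = 100, seed = 1, reverse = TRUE)
  expect_equal(rev$a, fwd$a)          # correlation is symmetric
  expect_false(isTRUE(all.equal(rev$b, fwd$b)))
})
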