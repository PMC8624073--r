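test_that("ANOVA decomposition matches the hand-computed 4x2 example", {
  x <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 9))
  a <- anova_decomposition(x)
  expect_equal(a$MSR, 46.375 / 3)
  expect_equal(a$MSC, 3.125)
  expect_equal(a$MSE, 0.125)
  expect_equal(unname(a$df), c(3L, 1L, 3L))
  expect_equal(a$ss[["total"]],
               a$ss[["rows"]] + a$ss[["cols"]] + a$ss[["error"]])
  # the estimate follows from plugging these mean squares into the formula
  est <- icc_a1(x)$estimate
  expect_equal(est, (a$MSR - a$MSE) /
                 (a$MSR + a$MSE + (2 / 4) * (a$MSC - a$MSE)))
  expect_equal(est, oracle_icc_a1(x))
})

test_that("identical columns give MSC = MSE = 0 and ICC exactly 1", {
  x <- cbind(c(1, 2, 3), c(1, 2, 3))
  a <- anova_decomposition(x)
  expect_equal(a$MSC, 0)
  expect_equal(a$MSE, 0)
  r <- icc_a1(x)
  expect_identical(r$estimate, 1)
  expect_identical(c(r$ci_low, r$ci_high), c(1, 1))
  expect_equal(r$category, "excellent")
})

test_that("constant matrices are flagged degenerate, not estimated", {
  x <- matrix(5, 4, 2)
  a <- anova_decomposition(x)
  expect_equal(unname(c(a$MSR, a$MSC, a$MSE)), c(0, 0, 0))
  r <- icc_a1(x)
  expect_true(r$degenerate)
  expect_true(is.na(r$estimate))
})

test_that("ICC(A,1) equals the sums-of-squares oracle on random matrices", {
  set.seed(314)
  for (i in 1:25) {
    n <- sample(4:12, 1); k <- sample(2:3, 1)
    x <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k)
    expect_equal(icc_a1(x)$estimate, oracle_icc_a1(x), tolerance = 1e-12)
  }
})

test_that("estimate, CI and p reproduce an independent reference implementation", {
  # frozen reference values computed with pingouin.intraclass_corr (ICC(A,1))
  # on this matrix
  x <- matrix(c(0.2462, -0.7196, 0.4772, 0.3812, -0.2214, -0.7079,
                -1.3558, -0.555, -0.4693, -0.1763, -0.644, -0.8851,
                -0.612, -0.9982, 1.1114, 1.2709, -1.4428, -0.3165,
                -1.2652, -0.3638), ncol = 2, byrow = TRUE)
  r <- icc_a1(x)
  expect_equal(r$estimate, 0.629407962902105, tolerance = 1e-12)
  expect_equal(r$p_value, 0.0227944782188606, tolerance = 1e-10)
  # the reference prints its CI rounded to 2 decimals
  expect_equal(round(r$ci_low, 2), 0.03)
  expect_equal(round(r$ci_high, 2), 0.89)
})

test_that("ICC(A,1) is invariant under common affine maps, sensitive to one-column shifts", {
  pm <- random_reliable_pairs(15, icc = 0.8, seed = 5)
  base <- icc_a1(pm)$estimate
  expect_equal(icc_a1(3.2 * unclass(pm) + 17)$estimate, base)
  shifted <- unclass(pm)
  shifted[, 2] <- shifted[, 2] + 2
  expect_lt(icc_a1(shifted)$estimate, base)
})

test_that("ICC on exchangeable null pairs is near zero on average", {
  set.seed(8)
  ests <- vapply(1:200, function(i) {
    icc_a1(log(unclass(simulate_null_pairs(60, 0.5, seed = i))))$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests)), 0.05)
})

test_that("reliability categories follow the published cutoffs and boundary conventions", {
  expect_equal(classify_reliability(c(0.99, 0.89, 0.51, 0.29)),
               c("excellent", "good", "moderate", "poor"))
  # boundary conventions: 0.5 opens moderate, 0.75 opens good, 0.90 is
  # still good, only > 0.90 is excellent; negatives are poor
  expect_equal(classify_reliability(c(0.4999, 0.5, 0.7499, 0.75, 0.90,
                                      0.9000001, 1, -0.3)),
               c("poor", "moderate", "moderate", "good", "good",
                 "excellent", "excellent", "poor"))
  expect_error(classify_reliability(1.01), "exceed")
  # total monotone step function: categories never step down as the
  # estimate increases
  grid <- seq(-0.5, 1, by = 0.01)
  lev <- match(classify_reliability(grid),
               c("poor", "moderate", "good", "excellent"))
  expect_true(all(diff(lev) >= 0))
})

test_that("incomplete matrices are rejected", {
  x <- cbind(c(1, NA, 3), c(4, 5, 6))
  expect_error(anova_decomposition(x), "complete")
  expect_error(icc_a1(x), "complete")
})
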