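test_that("Welch t-test matches hand-derived values and contracts", {
  # direct evaluation of the Welch formula on {1,2,3} vs {4,5,6}:
  # t = -3 / sqrt(2/3), df = 4, p = 2 * P(T_4 < t)
  r <- welchTTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)

  # identical samples
  expect_equal(welchTTest(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(welchTTest(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # antisymmetry
  a <- welchTTest(c(1, 5, 7), c(2, 2, 9, 4))
  b <- welchTTest(c(2, 2, 9, 4), c(1, 5, 7))
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)

  # degenerate contracts: zero variance in both samples
  d <- welchTTest(c(2, 2), c(2, 2))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)
  d2 <- welchTTest(c(3, 3), c(2, 2))
  expect_equal(d2$p_value, 0)
  expect_error(welchTTest(1, c(1, 2)), "at least 2")
})

test_that("rowWelchTest agrees with the scalar test row by row", {
  set.seed(42)
  mx <- matrix(rnorm(50, 1), 10, 5)
  my <- matrix(rnorm(40), 10, 4)
  rw <- rowWelchTest(mx, my)
  for (i in 1:10) {
    s <- welchTTest(mx[i, ], my[i, ])
    expect_equal(rw$statistic[i], s$statistic, tolerance = 1e-10)
    expect_equal(rw$p_value[i], s$p_value, tolerance = 1e-10)
    expect_equal(rw$df[i], s$df, tolerance = 1e-10)
  }
  # degenerate rows follow the scalar contract
  rw2 <- rowWelchTest(matrix(c(2, 2, 3, 3), 2, 2, byrow = TRUE),
                      matrix(c(2, 2, 1, 1), 2, 2, byrow = TRUE))
  expect_equal(rw2$p_value, c(1, 0))
})

test_that("BH adjustment: step-up hand computation, caps and monotonicity", {
  expect_equal(bhAdjust(0.5)$adjusted, 0.5)
  # hand step-up: 0.04*4/4, min(0.03*4/3, .) ... all collapse to 0.04
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04))$adjusted,
               rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5))$adjusted, rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  p <- runif(100)
  adj <- bhAdjust(p)$adjusted
  expect_true(all(adj >= p))
  # re-adjustment never lowers any value and stays capped at 1
  re <- bhAdjust(adj)$adjusted
  expect_true(all(re >= adj) && all(re <= 1))
  # idempotent on flat monotone inputs
  expect_equal(bhAdjust(rep(0.04, 4))$adjusted, rep(0.04, 4))
})

test_that("Spearman correlation: monotone, hand example, degenerate", {
  x <- c(0.3, 1.2, 5, 9)
  expect_equal(spearmanCor(x, 2 * x + 1)$estimate, 1)
  expect_equal(spearmanCor(x, -x)$estimate, -1)
  # 1 - 6 * sum(d^2) / (n(n^2-1)) with d = (0,1,-1,0): 1 - 12/60
  expect_equal(spearmanCor(c(1, 2, 3, 4), c(1, 3, 2, 4))$estimate, 0.8)
  dg <- spearmanCor(c(1, 1, 1), c(1, 2, 3))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$estimate))
  expect_error(spearmanCor(1:2, 1:2), "at least 3")
})

test_that("binomial test is exact against tail enumeration", {
  # P(X >= 7 | n = 10, p = 1/2) = 176/1024 by enumeration
  expect_equal(binomialTest(7, 10, 0.5, "greater")$p_value, 176 / 1024,
               tolerance = 1e-12)
  expect_equal(binomialTest(5, 5, 0.9, "greater")$p_value, 0.9^5,
               tolerance = 1e-12)
  expect_equal(binomialTest(0, 8, 0.3, "greater")$p_value, 1)
  expect_error(binomialTest(2, 10, 0), "strictly inside")
  expect_error(binomialTest(11, 10, 0.5), "0 <= k <= n")
  # exhaustive agreement with direct mass summation for n <= 12
  for (n in c(3, 7, 12)) for (p0 in c(0.1, 0.5, 0.9)) for (k in 0:n) {
    expect_equal(binomialTest(k, n, p0, "greater")$p_value,
                 sum(dbinom(k:n, n, p0)), tolerance = 1e-12)
    expect_equal(binomialTest(k, n, p0, "less")$p_value,
                 sum(dbinom(0:k, n, p0)), tolerance = 1e-12)
  }
})

test_that("chi-square 2x2 matches sum((O-E)^2/E) and is symmetric", {
  tab <- matrix(c(10, 30, 10, 150), 2, 2, byrow = TRUE)
  expect_equal(chiSquare2x2(tab)$statistic, 12.5, tolerance = 1e-12)
  expect_equal(chiSquare2x2(t(tab))$statistic, 12.5, tolerance = 1e-12)
  # table proportional to its margins: independence, statistic 0
  ind <- outer(c(2, 8), c(5, 15)) / 2
  r <- chiSquare2x2(ind)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)
  expect_error(chiSquare2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero margin")
  set.seed(11)
  for (i in 1:25) {
    tb <- matrix(rpois(4, 40) + 1, 2, 2)
    E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    expect_equal(chiSquare2x2(tb)$statistic, sum((tb - E)^2 / E),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U: exact enumeration and rank invariance", {
  # all 6 arrangements of ranks: P(U = 0) = 1/6, two-sided doubles it
  r <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(unname(r$statistic), 0)
  expect_equal(mannWhitneyU(1, 1)$p_value, 1)
  a <- mannWhitneyU(c(1, 4, 6), c(2, 3, 9))
  b <- mannWhitneyU(c(1, 4, 6) + 100, c(2, 3, 9) + 100)
  expect_equal(a$p_value, b$p_value)
  expect_error(mannWhitneyU(numeric(0), 1), "empty")
})

test_that("two-way ANOVA detects planted interactions and degenerates", {
  g <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:12)
  flat <- twoWayAnova(rep(1, nrow(g)), g$a, g$b)
  expect_equal(flat$interaction$p_value, 1)
  expect_equal(flat$factor_a$statistic, 0)

  set.seed(5)
  # additive effects only: interaction should stay null
  v_add <- 2 * (g$a == "y") + 1 * (g$b == "v") + rnorm(nrow(g), 0, 0.5)
  add <- twoWayAnova(v_add, g$a, g$b)
  expect_lt(add$factor_a$p_value, 1e-6)
  expect_lt(add$factor_b$p_value, 1e-3)

  # planted interaction of 2 noise SDs
  v_int <- v_add + 1 * (g$a == "y" & g$b == "v")
  int <- twoWayAnova(v_int, g$a, g$b)
  expect_lt(int$interaction$p_value, 0.05)

  expect_error(twoWayAnova(1:4, c("x", "x", "x", "x"), c("u", "v", "u", "v")),
               ">= 2 levels")
})

test_that("null p-values are approximately uniform (KS distance < 0.05)", {
  set.seed(202)
  p_welch <- replicate(1000, welchTTest(rnorm(10), rnorm(10))$p_value)
  ks <- suppressWarnings(ks.test(p_welch, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  p_sp <- replicate(1000, spearmanCor(rnorm(20), rnorm(20))$p_value)
  ks2 <- suppressWarnings(ks.test(p_sp, "punif"))
  expect_lt(unname(ks2$statistic), 0.05)
})
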