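# Group-comparison statistics: permutation global test, rank tests,
# chi-square, FDR adjustment, per-coordinate pipeline.

test_that("global composition test detects a gross single-part shift", {
  g <- null_groups(50, seed = 31)
  shifted <- g$b
  shifted[, 7] <- shifted[, 7] * 3
  shifted <- close_composition(shifted)
  res <- global_composition_test(g$a, shifted, n_perm = 999, seed = 1)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$n1, 50L)
  expect_equal(res$n2, 50L)
})

test_that("global composition test returns p = 1 for identical groups", {
  g <- null_groups(6, seed = 32)
  res <- global_composition_test(g$a, g$a, n_perm = 99, seed = 2)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(global_composition_test(g$a, g$b, n_perm = 50), "99")
})

test_that("global composition test is deterministic given the seed", {
  g <- null_groups(20, seed = 33)
  r1 <- global_composition_test(g$a, g$b, n_perm = 199, seed = 7)
  r2 <- global_composition_test(g$a, g$b, n_perm = 199, seed = 7)
  expect_identical(r1, r2)
})

test_that("mann_whitney matches exact enumeration and the normal tail", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)              # all of x below all of y
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)  # 2 of C(4,2) orderings

  expect_warning(r2 <- mann_whitney(c(2, 2, 2), c(2, 2)), "identical")
  expect_equal(r2$p_value, 1)

  x <- seq(0, 1, length.out = 30)
  r3 <- mann_whitney(x, x + 50)
  expect_lt(r3$p_value, 1e-5)
  # tie-corrected normal approximation oracle (continuity corrected)
  n1 <- 30; n2 <- 30
  u <- r3$statistic
  z <- (u - n1 * n2 / 2 + 0.5) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  expect_equal(r3$p_value, 2 * pnorm(z), tolerance = 1e-9)
})

test_that("kruskal_wallis agrees with mann_whitney for 2 groups and finds separation", {
  withr::with_seed(41, {
    x <- rnorm(25); y <- rnorm(25, 0.8)
  })
  kw <- kruskal_wallis(list(x, y))
  mw <- mann_whitney(x, y)
  expect_lt(abs(kw$p_value - mw$p_value), 0.02)

  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  k0 <- kruskal_wallis(same)
  expect_equal(k0$statistic, 0, tolerance = 1e-12)
  expect_equal(k0$p_value, 1, tolerance = 1e-12)

  far <- list(rnorm(10), rnorm(10, 10), rnorm(10, 20))
  expect_lt(kruskal_wallis(far)$p_value, 1e-4)
  expect_error(kruskal_wallis(list(1:5)), "2 groups")
})

test_that("chi_square reproduces the hand Pearson formula and scales linearly", {
  flat <- matrix(c(10, 10, 10, 10), 2)
  r0 <- chi_square(flat)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  tab <- matrix(c(20, 10, 10, 20), 2)
  r <- chi_square(tab)
  # hand evaluation: all expected cells 15, sum (O-E)^2/E = 4 * 25/15
  expect_equal(r$statistic, 4 * 25 / 15, tolerance = 1e-9)
  expect_equal(r$p_value, pchisq(20 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(chi_square(2 * tab)$statistic, 2 * r$statistic,
               tolerance = 1e-9)
  expect_warning(chi_square(matrix(c(1, 0, 0, 1), 2)), "below 1")
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  withr::with_seed(42, p <- runif(30))
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # order preserving
  perm <- sample(30)
  expect_equal(bh_adjust(p[perm]), adj[perm])      # input-order invariant
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("peakwise comparison is symmetric in the two cohorts", {
  g <- null_groups(30, seed = 51)
  ab <- peakwise_comparison(g$a, g$b)
  ba <- peakwise_comparison(g$b, g$a)
  expect_equal(nrow(ab), 45)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$p_adj, bh_adjust(ab$p_value))
})

test_that("peakwise comparison flags coordinates carrying an injected effect", {
  # shift ilr coordinates 40-45 of one cohort and check sensitivity
  comp <- random_compositions(1500, seed = 52)
  z <- ilr_transform(comp)
  za <- z[1:750, ]; zb <- z[751:1500, ]
  zb[, 40:45] <- zb[, 40:45] + 0.35
  a <- ilr_inverse(za); b <- ilr_inverse(zb)
  res <- peakwise_comparison(a, b)
  hits <- which(res$significant)
  expect_gte(sum(hits %in% 40:45), 0.8 * 6)   # at least 80% sensitivity
})
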