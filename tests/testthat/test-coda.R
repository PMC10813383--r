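# Simplex algebra: closure, zero replacement, log-ratio transforms and their
# inverses, rank correlations.

test_that("closure rescales proportionally, is idempotent and scale invariant", {
  v <- c(1, 1, 2, rep(0, 43))
  expect_equal(unname(close_composition(v)[1:3]), c(25, 25, 50))
  closed <- random_compositions(5, seed = 11)
  expect_equal(close_composition(closed), closed, tolerance = 1e-12)
  raw <- matrix(runif(3 * 46, 0.1, 5), 3, 46)
  expect_equal(close_composition(raw), close_composition(7.3 * raw),
               tolerance = 1e-12)
  expect_true(all(abs(rowSums(close_composition(raw)) - 100) < 1e-9))
  expect_error(close_composition(rep(0, 46)), "degenerate")
  expect_error(close_composition(c(-1, 2, 3)), "non-negative")
})

test_that("multiplicative zero replacement imputes half the column minimum", {
  comp <- random_compositions(4, seed = 2)
  expect_identical(replace_zeros(comp), comp)  # no zeros: untouched

  m <- random_compositions(4, seed = 3)
  m[, 46] <- c(0.02, 0.05, 0.04, 0)
  m <- close_composition(m)
  # row 4 keeps a zero after closure; column minimum positive recomputed
  min_pos <- min(m[m[, 46] > 0, 46])
  out <- replace_zeros(m)
  expect_equal(unname(out[4, 46]), 0.5 * min_pos, tolerance = 1e-12)
  expect_equal(unname(rowSums(out)), rep(100, 4), tolerance = 1e-9)
  expect_true(all(out > 0))
  expect_true(all(is.finite(ilr_transform(out))))

  bad <- m; bad[, 10] <- 0
  expect_error(replace_zeros(bad), "GP10")
})

test_that("ilr pivot coordinates match the closed-form scalar case", {
  expect_equal(unname(ilr_transform(rep(100 / 46, 46))), rep(0, 45),
               tolerance = 1e-12)
  expect_equal(unname(ilr_transform(c(75, 25))), sqrt(1 / 2) * log(3),
               tolerance = 1e-12)
})

test_that("ilr is an isometry for the Aitchison distance", {
  comp <- random_compositions(10, seed = 4)
  for (i in 1:5) {
    x <- comp[2 * i - 1, ]; y <- comp[2 * i, ]
    d_aitch <- sqrt(sum((clr_transform(x) - clr_transform(y))^2))
    d_ilr <- sqrt(sum((ilr_transform(x) - ilr_transform(y))^2))
    expect_equal(d_ilr, d_aitch, tolerance = 1e-10)
    expect_equal(aitchison_distance(x, y), d_aitch, tolerance = 1e-12)
  }
})

test_that("ilr_inverse round trips and averages to the compositional mean", {
  expect_equal(unname(ilr_inverse(rep(0, 45))), rep(100 / 46, 46),
               tolerance = 1e-12)
  comp <- random_compositions(100, seed = 5)
  back <- ilr_inverse(ilr_transform(comp))
  expect_lt(max(abs(back - comp)), 1e-9)
  # midpoint in ilr space = closed element-wise geometric mean
  x <- comp[1, ]; y <- comp[2, ]
  mid <- ilr_inverse((ilr_transform(x) + ilr_transform(y)) / 2)
  gmean <- close_composition(sqrt(x * y))
  expect_equal(unname(mid), unname(gmean), tolerance = 1e-9)
})

test_that("clr sums to zero and is the basis image of ilr", {
  expect_equal(unname(clr_transform(rep(100 / 46, 46))), rep(0, 46))
  comp <- random_compositions(20, seed = 6)
  cl <- clr_transform(comp)
  expect_lt(max(abs(rowSums(cl))), 1e-10)
  V <- ilr_basis(46)
  expect_equal(cl, ilr_transform(comp) %*% t(V), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unname(crossprod(V)), diag(45), tolerance = 1e-12)
  expect_error(clr_transform(c(1, 0, 2)), "positive")
})

test_that("spearman_ilr matches a rank-then-Pearson oracle and flags ties", {
  z <- matrix(c(0.1, 0.5, 0.3, 0.9, 0.2,
                1.0, 0.2, 0.6, 0.4, 0.8,
                5.0, 1.2, 3.1, 2.2, 4.0,
                0.3, 0.3, 0.3, 0.9, 0.1), 5, 4)
  r <- spearman_ilr(z)
  oracle <- cor(apply(z, 2, rank))
  expect_equal(unname(r), unname(oracle), tolerance = 1e-12)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 4))

  dup <- cbind(z, z[, 1])           # duplicated column: correlation 1
  expect_equal(spearman_ilr(dup)[1, 5], 1)
  neg <- cbind(z, -z[, 1])          # negated copy: correlation -1
  expect_equal(spearman_ilr(neg)[1, 5], -1)

  const <- cbind(z, rep(2, 5))
  expect_warning(rc <- spearman_ilr(const), "constant")
  expect_true(all(is.na(rc[5, -5])))
  expect_equal(rc[5, 5], 1)
})
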