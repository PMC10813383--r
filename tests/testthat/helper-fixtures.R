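# Shared fixtures: random compositions and independent oracles used across
# test files.

# n random strictly positive compositions closed to `total`, reproducible
random_compositions <- function(n, D = 46, total = 100, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(exp(rnorm(n * D)), n, D)
  })
  colnames(m) <- if (D == 46) gp_names() else paste0("part", seq_len(D))
  close_composition(m, total)
}

# independent Cox-de Boor recursion for a single B-spline basis function
cox_de_boor <- function(x, knots, i, ord) {
  if (ord == 1) {
    return(as.numeric(x >= knots[i] & x < knots[i + 1]))
  }
  a <- 0
  d1 <- knots[i + ord - 1] - knots[i]
  if (d1 > 0) a <- (x - knots[i]) / d1 * cox_de_boor(x, knots, i, ord - 1)
  b <- 0
  d2 <- knots[i + ord] - knots[i + 1]
  if (d2 > 0) b <- (knots[i + ord] - x) / d2 * cox_de_boor(x, knots, i + 1, ord - 1)
  a + b
}

# a small null cohort: two groups drawn from one distribution over the simplex
null_groups <- function(n_per_group, seed) {
  comp <- random_compositions(2 * n_per_group, seed = seed)
  list(a = comp[seq_len(n_per_group), , drop = FALSE],
       b = comp[-seq_len(n_per_group), , drop = FALSE])
}
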