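# Group-comparison statistics for compositional glycomics: a permutation-
# calibrated global two-sample test on clr means, per-coordinate rank tests,
# categorical tests and Benjamini-Hochberg FDR control.

test_result <- function(statistic, p_value, method, n1, n2 = NA_integer_, ...) {
  tibble::tibble(statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value),
                 method = method, n1 = as.integer(n1), n2 = as.integer(n2), ...)
}

# max-type statistic on clr columns: squared two-sample t numerators
max_t2_statistic <- function(clr_pooled, idx_a, keep) {
  a <- clr_pooled[idx_a, keep, drop = FALSE]
  b <- clr_pooled[-idx_a, keep, drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  d <- colMeans(a) - colMeans(b)
  va <- colSums(a^2) / na - colMeans(a)^2
  vb <- colSums(b^2) / nb - colMeans(b)^2
  # unbiased variances
  va <- va * na / (na - 1); vb <- vb * nb / (nb - 1)
  max(d^2 / (va / na + vb / nb))
}

#' Global two-sample test for high-dimensional compositions
#'
#' Tests whether two groups of 46-part glycan compositions share a common
#' center.  The statistic is the maximum over clr coordinates of the squared
#' standardized mean difference (a max-type statistic suited to sparse
#' alternatives in high dimension); its null distribution is calibrated by
#' random relabelling of subjects, which is exact under exchangeability at
#' any sample size.
#'
#' @param x,y Composition matrices or data frames with GP columns, one
#'   subject per row, strictly positive and closed.
#' @param n_perm Number of permutations (at least 99; default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A one-row tibble with `statistic`, `p_value`
#'   (`(1 + #\{M* >= M\}) / (n_perm + 1)`), `method`, group sizes and
#'   `n_perm`.
#' @export
global_composition_test <- function(x, y, n_perm = 999, seed = 1) {
  if (n_perm < 99) abort("n_perm must be at least 99")
  x <- as_gp_matrix_any(x); y <- as_gp_matrix_any(y)
  if (nrow(x) < 5 || nrow(y) < 5) abort("each group needs at least 5 subjects")
  pooled <- clr_transform(rbind(x, y))
  na <- nrow(x); n <- nrow(pooled)
  keep <- apply(pooled, 2, function(v) stats::var(v) > 0)
  if (!all(keep)) {
    warn(paste0(sum(!keep), " clr column(s) with zero variance skipped"))
  }
  if (!any(keep)) abort("no clr column with positive variance")
  obs <- max_t2_statistic(pooled, seq_len(na), keep)
  old <- .Random.seed_save(seed)
  on.exit(.Random.seed_restore(old))
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, na)
    if (max_t2_statistic(pooled, idx, keep) >= obs) exceed <- exceed + 1L
  }
  test_result(obs, (1 + exceed) / (n_perm + 1),
              "permutation max-t2 on clr means", na, n - na,
              n_perm = as.integer(n_perm))
}

# accept matrix of any width (not just 46 GPs) for the clr-based test
as_gp_matrix_any <- function(x) {
  if (is.data.frame(x) && all(GP_NAMES %in% names(x))) return(as_gp_matrix(x))
  m <- as.matrix(x); storage.mode(m) <- "double"; m
}

# seed bracketing helpers: set a reproducible stream, restore afterwards
.Random.seed_save <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided rank test with midrank ties: exact enumeration when the pooled
#' sample has at most 12 observations and no ties, otherwise the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param x,y Numeric samples, each of size at least 2.
#' @return One-row tibble with the U statistic, p-value and group sizes.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # exact p = 1/3
mann_whitney <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("each sample needs >= 2 values")
  pooled <- c(x, y)
  if (diff(range(pooled)) == 0) {
    warn("all values identical; p = 1")
    return(test_result(length(x) * length(y) / 2, 1, "Mann-Whitney",
                       length(x), length(y)))
  }
  exact <- (length(pooled) <= 12) && !anyDuplicated(pooled)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  test_result(unname(wt$statistic), wt$p.value, "Mann-Whitney",
              length(x), length(y))
}

#' Kruskal-Wallis rank test
#'
#' @param groups List of two or more numeric samples, each of size >= 2.
#' @return One-row tibble with the tie-corrected H statistic, chi-square
#'   p-value on `k - 1` degrees of freedom and total sample size.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) abort("need >= 2 groups")
  if (any(lengths(groups) < 2)) abort("each group needs >= 2 values")
  kt <- stats::kruskal.test(groups)
  test_result(unname(kt$statistic), kt$p.value, "Kruskal-Wallis",
              sum(lengths(groups)), df = unname(kt$parameter))
}

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson statistic on `(r-1)(c-1)` degrees of freedom.  A
#' warning column flags tables with an expected cell below 1.
#'
#' @param contingency Matrix of non-negative counts.
#' @return One-row tibble with statistic, p-value, df and a
#'   `low_expected` flag.
#' @export
chi_square <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0) || any(m != round(m))) abort("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("contingency table has an empty row or column")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  low <- any(ct$expected < 1)
  if (low) warn("expected cell count below 1; chi-square approximation poor")
  test_result(unname(ct$statistic), ct$p.value, "Pearson chi-square",
              sum(m), df = unname(ct$parameter), low_expected = low)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: sorted p-values are multiplied by
#' `m / rank` and cumulative minima taken from the largest down, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-coordinate comparison of two cohorts
#'
#' Runs a Mann-Whitney test on each of the 45 ilr pivot coordinates of the
#' two cohorts and controls the FDR across coordinates by Benjamini-Hochberg.
#' Note that single pivot coordinates depend on the fixed GP1..GP46 peak
#' order: coordinate `z_i` contrasts peak `i` against all later peaks.
#'
#' @param x,y Data frames with GP columns or composition matrices.
#' @param alpha Significance level for the adjusted flag (default 0.05).
#' @return Tibble with one row per coordinate: `coordinate`, `peak` (the
#'   pivot peak), `statistic`, `p_value`, `p_adj`, `significant`.
#' @export
peakwise_comparison <- function(x, y, alpha = 0.05) {
  zx <- cohort_ilr(x); zy <- cohort_ilr(y)
  res <- purrr::map_dfr(seq_len(ncol(zx)), function(j) {
    mw <- mann_whitney(zx[, j], zy[, j])
    tibble::tibble(coordinate = paste0("z", j), peak = GP_NAMES[j],
                   statistic = mw$statistic, p_value = mw$p_value)
  })
  res$p_adj <- bh_adjust(res$p_value)
  res$significant <- res$p_adj < alpha
  res
}

# data frame / matrix of compositions -> ilr matrix
cohort_ilr <- function(x) {
  m <- as_gp_matrix_any(x)
  if (ncol(m) == N_PEAKS) {
    ilr_transform(replace_zeros(close_composition(m)))
  } else {
    m  # already ilr coordinates
  }
}
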