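# broom-style tidy()/glance() methods for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a robust PCA
#'
#' One row per component with eigenvalue and explained-variance fractions.
#'
#' @param x A `robust_pca`.
#' @param ... Unused.
#' @return A tibble with `component`, `eigenvalue`, `explained_fraction`,
#'   `cumulative_fraction`.
#' @exportS3Method generics::tidy
tidy.robust_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 explained_fraction = x$explained_fraction,
                 cumulative_fraction = cumsum(x$explained_fraction))
}

#' @rdname tidy.robust_pca
#' @exportS3Method generics::glance
glance.robust_pca <- function(x, ...) {
  tibble::tibble(n = x$n, method = x$method, h_fraction = x$h_fraction,
                 n_retained = sum(x$weights),
                 pc12_fraction = sum(x$explained_fraction[1:2]))
}

#' Tidy a K-means clustering
#'
#' One row per cluster with size and the simple-glycan mass of its centroid.
#'
#' @param x A `glyco_kmeans`.
#' @param ... Unused.
#' @return A tibble with `cluster`, `size`, `gp1_11_pct`.
#' @exportS3Method generics::tidy
tidy.glyco_kmeans <- function(x, ...) {
  tibble::tibble(cluster = seq_len(x$k), size = x$sizes,
                 gp1_11_pct = rowSums(x$centroid_composition[, 1:11, drop = FALSE]))
}

#' @rdname tidy.glyco_kmeans
#' @exportS3Method generics::glance
glance.glyco_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, wss = x$wss, totss = x$totss,
                 explained = 1 - x$wss / x$totss)
}

#' Tidy a penalized spline fit
#'
#' One row per basis coefficient with its standard error.
#'
#' @param x A `psmooth_fit` or `beta_smooth`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`.
#' @exportS3Method generics::tidy
tidy.psmooth_fit <- function(x, ...) {
  tibble::tibble(term = paste0("b", seq_along(x$coefficients)),
                 estimate = x$coefficients,
                 std_error = sqrt(diag(x$coef_covariance)))
}

#' @rdname tidy.psmooth_fit
#' @exportS3Method generics::glance
glance.psmooth_fit <- function(x, ...) {
  tibble::tibble(n = x$n, lambda = x$lambda, edf = x$edf,
                 sigma = sqrt(x$sigma2), gcv = x$gcv)
}

#' @rdname tidy.psmooth_fit
#' @exportS3Method generics::tidy
tidy.beta_smooth <- function(x, ...) {
  tibble::tibble(term = paste0("b", seq_along(x$coefficients)),
                 estimate = x$coefficients,
                 std_error = sqrt(diag(x$coef_covariance)))
}

#' @rdname tidy.psmooth_fit
#' @exportS3Method generics::glance
glance.beta_smooth <- function(x, ...) {
  tibble::tibble(n = x$n, lambda = x$lambda, edf = x$edf, phi = x$phi,
                 log_lik = x$loglik, iterations = x$iters)
}
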