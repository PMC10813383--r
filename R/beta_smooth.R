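# Penalized beta-response smooths for bounded glycan traits (core fucose,
# outer-arm fucose, oligomannose expressed as fractions of total area).
# Mean mu = logistic(B beta) with a second-order difference penalty on beta,
# constant precision phi, fitted by penalized Fisher scoring; lambda by GCV
# on the working penalized least-squares problem.

beta_loglik <- function(y, mu, phi) {
  p <- mu * phi; q <- (1 - mu) * phi
  sum(lgamma(phi) - lgamma(p) - lgamma(q) +
        (p - 1) * log(y) + (q - 1) * log1p(-y))
}

#' Penalized beta-response smooth for bounded traits
#'
#' Models a response in (0, 1) as beta-distributed with logit-linked mean
#' `mu(x) = logistic(B(x) beta)` and constant precision `phi`.  `beta` is
#' estimated by penalized Fisher scoring with a second-order difference
#' penalty; the smoothing parameter is selected by GCV on the working model,
#' and `phi` by profile maximum likelihood.  When `sex` is supplied the model
#' is fitted separately per sex (a factor-per-curve parameterization) and a
#' `beta_smooth_sexwise` object is returned.
#'
#' @param x Covariate (age in years).
#' @param y Response strictly inside (0, 1); trait percentages should be
#'   divided by 100 first.  Boundary values are nudged inward by 1e-6 with a
#'   warning.
#' @param sex Optional factor with levels `"M"`/`"F"` for per-sex fits.
#' @param n_basis,degree,penalty_order,lambda_grid Smoothing setup, as in
#'   [fit_psmooth()].
#' @param max_iter Maximum Fisher-scoring iterations (default 200).
#' @return A `beta_smooth` object (or `beta_smooth_sexwise` list of them)
#'   supporting `predict()`, `tidy()`, `glance()` and
#'   [sex_difference_windows()].
#' @export
fit_beta_smooth <- function(x, y, sex = NULL, n_basis = 10, degree = 3,
                            penalty_order = 2,
                            lambda_grid = default_lambda_grid(),
                            max_iter = 200) {
  if (!is.null(sex)) {
    sex <- as.character(sex)
    fits <- lapply(setNames(c("M", "F"), c("M", "F")), function(s) {
      fit_beta_smooth(x[sex == s], y[sex == s], NULL, n_basis, degree,
                      penalty_order, lambda_grid, max_iter)
    })
    return(structure(fits, class = "beta_smooth_sexwise"))
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (any(y <= 0 | y >= 1)) {
    warn("responses on the boundary of (0,1) nudged inward by 1e-6")
    y <- pmin(pmax(y, 1e-6), 1 - 1e-6)
  }
  if (length(x) < 20) abort("need at least 20 observations")
  x_range <- range(x)
  B <- bspline_basis(x, n_basis, degree, x_range)
  P <- difference_penalty(n_basis, penalty_order)
  n <- length(y)

  ystar <- stats::qlogis(y)
  eta <- rep(stats::qlogis(mean(y)), n)
  mu <- stats::plogis(eta)
  phi <- max(mean(mu * (1 - mu)) / stats::var(y) - 1, 1)
  lambda <- stats::median(lambda_grid)
  trace <- numeric(0)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    p1 <- mu * phi; q1 <- (1 - mu) * phi
    mustar <- digamma(p1) - digamma(q1)
    v <- trigamma(p1) + trigamma(q1)
    dmu <- mu * (1 - mu)
    w <- phi^2 * v * dmu^2          # Fisher weights wrt eta
    z <- eta + (ystar - mustar) / (phi * v * dmu)  # working response
    sw <- sqrt(w)
    Bw <- B * sw
    BtWB <- crossprod(Bw)
    BtWz <- crossprod(Bw, sw * z)
    # GCV over lambda on the working model
    gcv <- vapply(lambda_grid, function(l) {
      A <- BtWB + l * P
      R <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(R)) return(Inf)
      beta_l <- backsolve(R, forwardsolve(t(R), BtWz))
      edf <- sum(diag(chol2inv(R) %*% BtWB))
      rss <- sum(w * (z - drop(B %*% beta_l))^2)
      n * rss / (n - edf)^2
    }, numeric(1))
    lambda <- lambda_grid[which.min(gcv)]
    A <- BtWB + lambda * P
    beta <- drop(solve(A, BtWz))
    eta_new <- drop(B %*% beta)
    delta <- max(abs(eta_new - eta))
    eta <- eta_new
    mu <- stats::plogis(pmin(pmax(eta, -30), 30))
    # profile MLE for phi given mu
    phi <- stats::optimize(function(lp) -beta_loglik(y, mu, exp(lp)),
                           interval = c(log(0.1), log(1e5)))$minimum
    phi <- exp(phi)
    trace <- c(trace, delta)
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(paste0("beta smooth did not converge in ", max_iter,
                 " iterations; last deltas: ",
                 paste(signif(utils::tail(trace, 5), 3), collapse = ", ")))
  }
  Ainv <- solve(A)
  structure(list(coefficients = beta, lambda = lambda, phi = phi,
                 coef_covariance = Ainv %*% BtWB %*% Ainv,
                 edf = sum(diag(Ainv %*% BtWB)),
                 loglik = beta_loglik(y, mu, phi),
                 x_range = x_range, n_basis = n_basis, degree = degree,
                 penalty_order = penalty_order, n = n, iters = length(trace)),
            class = "beta_smooth")
}

#' @export
print.beta_smooth <- function(x, ...) {
  cat("Penalized beta-response smooth (logit link)\n")
  cat(sprintf("  n = %d, phi = %.2f, lambda = %.4g, edf = %.2f, iters = %d\n",
              x$n, x$phi, x$lambda, x$edf, x$iters))
  invisible(x)
}

#' @export
print.beta_smooth_sexwise <- function(x, ...) {
  cat("Per-sex beta-response smooths\n")
  for (s in names(x)) { cat(sprintf(" [%s] ", s)); print(x[[s]]) }
  invisible(x)
}

#' Predict from a beta-response smooth
#'
#' @param object A `beta_smooth`.
#' @param newdata Covariate values (clamped to the fitted range).
#' @param ... Unused.
#' @return Tibble with `x`, link-scale `fit` and `se`, and `mu`, `lower95`,
#'   `upper95` on the (0,1) response scale.
#' @export
predict.beta_smooth <- function(object, newdata, ...) {
  x <- pmin(pmax(newdata, object$x_range[1]), object$x_range[2])
  B <- bspline_basis(x, object$n_basis, object$degree, object$x_range)
  fit <- drop(B %*% object$coefficients)
  se <- sqrt(pmax(rowSums((B %*% object$coef_covariance) * B), 0))
  tibble::tibble(x = newdata, fit = fit, se = se,
                 mu = stats::plogis(fit),
                 lower95 = stats::plogis(fit - 1.96 * se),
                 upper95 = stats::plogis(fit + 1.96 * se))
}

#' @export
sex_difference_windows.beta_smooth_sexwise <- function(object, target = NULL,
                                                       age_grid = NULL) {
  rng <- c(max(object$M$x_range[1], object$F$x_range[1]),
           min(object$M$x_range[2], object$F$x_range[2]))
  if (is.null(age_grid)) age_grid <- seq(rng[1], rng[2], length.out = 200)
  pm <- predict(object$M, age_grid)
  pf <- predict(object$F, age_grid)
  d <- pm$fit - pf$fit
  sd <- sqrt(pm$se^2 + pf$se^2)
  runs_to_windows(abs(d) > 1.96 * sd, age_grid)
}
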