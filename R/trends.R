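# Penalized-spline age-trend models.  Peaks are modelled on the ilr scale,
# one smooth per coordinate and sex, and curves are mapped back to the
# percentage scale through the inverse ilr transform with Monte-Carlo
# uncertainty propagation; bounded traits get beta-response smooths
# (beta_smooth.R).

#' B-spline basis on equally spaced knots
#'
#' Builds an `n_basis`-column B-spline design matrix of the given degree on
#' equally spaced knots spanning `[min(x), max(x)]` (a partition of unity:
#' rows sum to 1).  This is the basis underlying all smooths in the package.
#'
#' @param x Numeric vector of evaluation points.
#' @param n_basis Number of basis functions (at least `degree + 1`).
#' @param degree Spline degree (default 3, cubic).
#' @param x_range Optional range to span instead of `range(x)` (used to
#'   evaluate a fitted basis at new points).
#' @return Numeric matrix, `length(x)` rows by `n_basis` columns.
#' @export
bspline_basis <- function(x, n_basis = 10, degree = 3, x_range = range(x)) {
  if (any(!is.finite(x))) abort("x must be finite")
  if (n_basis < degree + 1) abort("n_basis must be at least degree + 1")
  xl <- x_range[1]; xr <- x_range[2]
  nseg <- n_basis - degree
  dx <- (xr - xl) / nseg
  knots <- xl + dx * ((-degree):(nseg + degree))
  # nudge the last knot so the right boundary point stays in-support
  knots[length(knots)] <- knots[length(knots)] + 1e-8 * max(1, abs(xr))
  if (any(x < xl) || any(x > xr)) abort("x outside the basis range")
  splines::splineDesign(knots, x, ord = degree + 1, outer.ok = TRUE)
}

# order-d difference penalty matrix for n_basis coefficients
difference_penalty <- function(n_basis, order = 2) {
  D <- diff(diag(n_basis), differences = order)
  crossprod(D)
}

default_lambda_grid <- function() 10^seq(-3, 6, length.out = 28)

# Core penalized least-squares fit for a shared basis and one or many
# response columns.  lambda is selected per column by GCV
# n * RSS / (n - edf)^2; the hat-trace per lambda is shared across columns.
psmooth_engine <- function(B, Y, penalty_order = 2, lambda_grid = default_lambda_grid()) {
  Y <- as.matrix(Y)
  n <- nrow(B); nb <- ncol(B); q <- ncol(Y)
  P <- difference_penalty(nb, penalty_order)
  BtB <- crossprod(B)
  BtY <- crossprod(B, Y)
  n_lam <- length(lambda_grid)
  gcv <- matrix(NA_real_, n_lam, q)
  betas <- vector("list", n_lam)
  edfs <- numeric(n_lam)
  for (l in seq_len(n_lam)) {
    A <- BtB + lambda_grid[l] * P
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) {
      if (n < nb) abort("singular system: increase lambda or reduce n_basis")
      next
    }
    Ainv_BtB <- chol2inv(R) %*% BtB
    edfs[l] <- sum(diag(Ainv_BtB))
    beta <- backsolve(R, forwardsolve(t(R), BtY))
    rss <- colSums((Y - B %*% beta)^2)
    gcv[l, ] <- n * rss / (n - edfs[l])^2
    betas[[l]] <- beta
  }
  pick <- apply(gcv, 2, which.min)
  out <- lapply(seq_len(q), function(j) {
    l <- pick[j]
    lambda <- lambda_grid[l]
    beta <- betas[[l]][, j]
    A <- BtB + lambda * P
    Ainv <- chol2inv(chol(A))
    resid <- Y[, j] - B %*% beta
    edf <- edfs[l]
    sigma2 <- sum(resid^2) / max(n - edf, 1)
    list(coefficients = beta,
         lambda = lambda,
         edf = edf,
         sigma2 = sigma2,
         gcv = gcv[l, j],
         coef_covariance = sigma2 * Ainv %*% BtB %*% Ainv)
  })
  out
}

#' Fit a penalized B-spline smooth
#'
#' Minimizes `||y - B beta||^2 + lambda ||D2 beta||^2` where `B` is a cubic
#' B-spline basis on equally spaced knots and `D2` the second-order
#' difference operator, so constants and straight lines are never penalized.
#' The smoothing parameter is chosen by generalized cross-validation over a
#' log-spaced grid; coefficient uncertainty uses the sandwich covariance
#' `sigma^2 (B'B + lambda P)^{-1} B'B (B'B + lambda P)^{-1}`.
#'
#' @param x Covariate (e.g. age in years).
#' @param y Response vector.
#' @param n_basis Number of B-spline basis functions (default 10).
#' @param degree Spline degree (default 3).
#' @param penalty_order Difference-penalty order (default 2).
#' @param lambda_grid Grid of candidate smoothing parameters.
#' @return An object of class `psmooth_fit` with coefficients, selected
#'   `lambda`, effective degrees of freedom `edf`, GCV score and coefficient
#'   covariance; supports `predict()`, `tidy()`, `glance()` and `autoplot()`.
#' @export
fit_psmooth <- function(x, y, n_basis = 10, degree = 3, penalty_order = 2,
                        lambda_grid = default_lambda_grid()) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 20) abort("need at least 20 observations")
  if (diff(range(x)) <= 0) abort("x must span an interval")
  x_range <- range(x)
  B <- bspline_basis(x, n_basis, degree, x_range)
  eng <- psmooth_engine(B, y, penalty_order, lambda_grid)[[1]]
  structure(c(eng, list(x_range = x_range, n_basis = n_basis, degree = degree,
                        penalty_order = penalty_order, n = length(x))),
            class = "psmooth_fit")
}

#' @export
print.psmooth_fit <- function(x, ...) {
  cat("Penalized B-spline smooth\n")
  cat(sprintf("  n = %d, basis = %d (degree %d), penalty order %d\n",
              x$n, x$n_basis, x$degree, x$penalty_order))
  cat(sprintf("  lambda (GCV) = %.4g, edf = %.2f, sigma = %.4g\n",
              x$lambda, x$edf, sqrt(x$sigma2)))
  invisible(x)
}

#' Predict from a penalized spline fit
#'
#' @param object A `psmooth_fit`.
#' @param newdata Numeric vector of covariate values (clamped to the fitted
#'   range).
#' @param ... Unused.
#' @return Tibble with `x`, `fit`, `se`, `lower95`, `upper95`.
#' @export
predict.psmooth_fit <- function(object, newdata, ...) {
  x <- pmin(pmax(newdata, object$x_range[1]), object$x_range[2])
  B <- bspline_basis(x, object$n_basis, object$degree, object$x_range)
  fit <- drop(B %*% object$coefficients)
  se <- sqrt(pmax(rowSums((B %*% object$coef_covariance) * B), 0))
  tibble::tibble(x = newdata, fit = fit, se = se,
                 lower95 = fit - 1.96 * se, upper95 = fit + 1.96 * se)
}

#' Per-sex smooth age trends for all ilr coordinates
#'
#' For each of the 45 ilr pivot coordinates and each sex separately, fits a
#' penalized B-spline smooth of the coordinate against age.  All coordinates
#' of one sex share the basis (ages are common), but each coordinate gets its
#' own GCV-selected smoothing parameter.
#'
#' @param data Cohort data frame with `sex` (`"M"`/`"F"`), `age` and GP
#'   columns (or pre-computed `z1..z45` columns).
#' @param n_basis,degree,penalty_order,lambda_grid Passed to the smoother.
#' @return An object of class `sexwise_trends`: per-sex coefficient sets for
#'   all 45 coordinates, for use with [predict_composition_curve()] and
#'   [sex_difference_windows()].
#' @export
fit_sexwise_trends <- function(data, n_basis = 10, degree = 3,
                               penalty_order = 2,
                               lambda_grid = default_lambda_grid()) {
  stopifnot(is.data.frame(data), all(c("sex", "age") %in% names(data)))
  sexes <- c("M", "F")
  if (!all(sexes %in% data$sex)) abort("both sexes must be present")
  zcols <- paste0("z", 1:(N_PEAKS - 1))
  Z <- if (all(zcols %in% names(data))) {
    as.matrix(data[zcols])
  } else {
    ilr_transform(replace_zeros(close_composition(as_gp_matrix(data))))
  }
  fits <- lapply(setNames(sexes, sexes), function(s) {
    rows <- data$sex == s
    if (sum(rows) < 50) abort(paste0("fewer than 50 subjects of sex ", s))
    age <- data$age[rows]
    x_range <- range(age)
    B <- bspline_basis(age, n_basis, degree, x_range)
    eng <- psmooth_engine(B, Z[rows, , drop = FALSE], penalty_order, lambda_grid)
    list(engine = eng, x_range = x_range, n = sum(rows))
  })
  structure(list(fits = fits, n_basis = n_basis, degree = degree,
                 penalty_order = penalty_order),
            class = "sexwise_trends")
}

#' @export
print.sexwise_trends <- function(x, ...) {
  cat("Sex-wise ilr age-trend smooths (45 coordinates)\n")
  for (s in names(x$fits)) {
    f <- x$fits[[s]]
    cat(sprintf("  sex %s: n = %d, ages %.0f-%.0f, median edf = %.2f\n", s,
                f$n, f$x_range[1], f$x_range[2],
                stats::median(vapply(f$engine, `[[`, 0, "edf"))))
  }
  invisible(x)
}

# evaluate one sex's coordinate smooths: mean matrix (grid x 45) and,
# optionally, coefficient draws
sexwise_eval <- function(object, sex, age_grid) {
  f <- object$fits[[sex]]
  if (is.null(f)) abort(paste0("no fit for sex ", sex))
  x <- pmin(pmax(age_grid, f$x_range[1]), f$x_range[2])
  B <- bspline_basis(x, object$n_basis, object$degree, f$x_range)
  mu <- vapply(f$engine, function(e) drop(B %*% e$coefficients),
               numeric(length(x)))
  se <- vapply(f$engine,
               function(e) sqrt(pmax(rowSums((B %*% e$coef_covariance) * B), 0)),
               numeric(length(x)))
  list(B = B, mean = matrix(mu, nrow = length(x)),
       se = matrix(se, nrow = length(x)), engine = f$engine)
}

#' Back-transform fitted ilr trends to composition curves
#'
#' Evaluates one sex's 45 coordinate smooths on an age grid, applies the
#' inverse ilr transform to obtain mean peak-abundance curves on the percent
#' scale (closing to 100 at every age), and propagates coefficient
#' uncertainty by Monte-Carlo: coefficients are drawn from their Gaussian
#' sampling distribution, each draw is back-transformed, and pointwise
#' 2.5/97.5 percentiles per peak form the 95% band.
#'
#' @param object A `sexwise_trends` fit.
#' @param sex `"M"` or `"F"`.
#' @param age_grid Ages at which to evaluate (years).
#' @param n_draws Monte-Carlo draws (at least 100; default 1000).
#' @param seed Integer seed for the draws.
#' @return Tibble with columns `peak`, `sex`, `age`, `mean`, `lower95`,
#'   `upper95` (percent units).
#' @export
predict_composition_curve <- function(object, sex, age_grid, n_draws = 1000,
                                      seed = 1) {
  if (n_draws < 100) abort("n_draws must be at least 100")
  ev <- sexwise_eval(object, sex, age_grid)
  g <- length(age_grid)
  mean_comp <- ilr_inverse(ev$mean)  # g x 46
  old <- .Random.seed_save(seed)
  on.exit(.Random.seed_restore(old))
  nb <- length(ev$engine[[1]]$coefficients)
  # draws per coordinate: curve_draws[draw, age, coord]
  curves <- array(0, c(n_draws, g, N_PEAKS - 1))
  for (j in seq_along(ev$engine)) {
    e <- ev$engine[[j]]
    Lc <- tryCatch(chol(e$coef_covariance + 1e-12 * diag(nb)),
                   error = function(err) NULL)
    draws <- matrix(rnorm(n_draws * nb), n_draws, nb)
    betas <- if (is.null(Lc)) {
      matrix(e$coefficients, n_draws, nb, byrow = TRUE)
    } else {
      sweep(draws %*% Lc, 2, e$coefficients, `+`)
    }
    curves[, , j] <- betas %*% t(ev$B)
  }
  lower <- upper <- matrix(0, g, N_PEAKS)
  for (a in seq_len(g)) {
    comp_draws <- ilr_inverse(curves[, a, ])  # n_draws x 46
    qs <- apply(comp_draws, 2, stats::quantile, probs = c(0.025, 0.975))
    lower[a, ] <- qs[1, ]
    upper[a, ] <- qs[2, ]
  }
  tibble::tibble(
    peak = rep(GP_NAMES, each = g),
    sex = sex,
    age = rep(age_grid, N_PEAKS),
    mean = as.vector(mean_comp),
    lower95 = as.vector(lower),
    upper95 = as.vector(upper))
}

#' Age windows of significant sex difference
#'
#' Computes the male minus female difference curve on the model's link/ilr
#' scale with pointwise variance equal to the sum of the two fits' variances,
#' and returns the maximal age runs where the pointwise 95% interval
#' `d +/- 1.96 sd` excludes zero.
#'
#' @param object A `sexwise_trends` fit (use `target = "z<i>"` or an ilr
#'   coordinate index) or a `beta_smooth` fit with a sex factor.
#' @param target Coordinate name/index for `sexwise_trends`; ignored for
#'   beta smooths.
#' @param age_grid Evaluation grid (default 200 points over the common
#'   fitted range).
#' @return Tibble with columns `start`, `end` (years); zero rows when no
#'   significant window exists.
#' @export
sex_difference_windows <- function(object, target = NULL, age_grid = NULL) {
  UseMethod("sex_difference_windows")
}

#' @export
sex_difference_windows.sexwise_trends <- function(object, target = NULL,
                                                  age_grid = NULL) {
  j <- if (is.character(target)) as.integer(sub("^z", "", target)) else as.integer(target)
  if (is.na(j) || j < 1 || j > N_PEAKS - 1) abort("target must name an ilr coordinate")
  rng <- c(max(vapply(object$fits, function(f) f$x_range[1], 0)),
           min(vapply(object$fits, function(f) f$x_range[2], 0)))
  if (is.null(age_grid)) age_grid <- seq(rng[1], rng[2], length.out = 200)
  em <- sexwise_eval(object, "M", age_grid)
  ef <- sexwise_eval(object, "F", age_grid)
  d <- em$mean[, j] - ef$mean[, j]
  sd <- sqrt(em$se[, j]^2 + ef$se[, j]^2)
  runs_to_windows(abs(d) > 1.96 * sd, age_grid)
}

# contiguous TRUE runs -> (start, end) age intervals
runs_to_windows <- function(flag, grid) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(start = grid[starts[keep]], end = grid[ends[keep]])
}
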