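# Penalized-spline machinery and the sex-wise ilr trend pipeline.

test_that("bspline_basis is a partition of unity and matches Cox-de Boor", {
  withr::with_seed(61, x <- runif(80, 18, 91))
  for (deg in 0:3) {
    B <- bspline_basis(x, n_basis = 8, degree = deg)
    expect_equal(unname(rowSums(B)), rep(1, 80), tolerance = 1e-12)
    expect_equal(ncol(B), 8)
  }
  # degree 0 with 4 bins: indicator basis
  B0 <- bspline_basis(c(18, 30, 50, 70, 90.9), n_basis = 4, degree = 0,
                      x_range = c(18, 91))
  expect_true(all(rowSums(B0 > 0) == 1))
  expect_equal(unname(colSums(B0)), c(2, 1, 1, 1))

  # independent recursive evaluation
  n_basis <- 7; deg <- 3
  xr <- c(0, 10); nseg <- n_basis - deg; dx <- diff(xr) / nseg
  knots <- xr[1] + dx * ((-deg):(nseg + deg))
  xs <- seq(0.5, 9.5, by = 0.75)
  B <- bspline_basis(xs, n_basis, deg, xr)
  oracle <- sapply(seq_len(n_basis), function(i) cox_de_boor(xs, knots, i, deg + 1))
  expect_equal(unname(B), unname(oracle), tolerance = 1e-10)

  expect_error(bspline_basis(x, n_basis = 3, degree = 3), "n_basis")
})

test_that("order-2 penalty leaves constants and lines unshrunk", {
  withr::with_seed(62, x <- sort(runif(100, 18, 91)))
  fc <- fit_psmooth(x, rep(3.7, 100))
  expect_equal(predict(fc, x)$fit, rep(3.7, 100), tolerance = 1e-8)
  y_lin <- 0.4 * x - 2
  fl <- fit_psmooth(x, y_lin, lambda_grid = c(1e-2, 1e2, 1e8))
  expect_equal(predict(fl, x)$fit, y_lin, tolerance = 1e-6)
})

test_that("fit_psmooth recovers a smooth signal and agrees with a GAM fit", {
  withr::with_seed(63, {
    x <- runif(500, 0, 60)
    truth <- sin(x / 10)
    y <- truth + rnorm(500, sd = 0.1)
  })
  fit <- fit_psmooth(x, y)
  grid <- seq(1, 59, length.out = 50)
  pred <- predict(fit, grid)
  expect_lt(sqrt(mean((pred$fit - sin(grid / 10))^2)), 0.05)
  expect_true(all(pred$lower95 <= pred$fit & pred$fit <= pred$upper95))
  # independent route: mgcv thin-plate GAM on the same data
  gam_fit <- mgcv::gam(y ~ s(x, k = 10))
  gam_pred <- as.numeric(predict(gam_fit, data.frame(x = grid)))
  expect_lt(max(abs(pred$fit - gam_pred)), 0.05)
  # deterministic refit
  expect_identical(fit$coefficients, fit_psmooth(x, y)$coefficients)
})

test_that("GCV picks heavier smoothing for pure noise than for signal", {
  lambdas <- sapply(1:5, function(s) {
    withr::with_seed(70 + s, {
      x <- runif(300, 0, 60)
      noise <- rnorm(300)
      signal <- 3 * sin(x / 8) + rnorm(300, sd = 0.2)
    })
    c(noise = fit_psmooth(x, noise)$lambda,
      signal = fit_psmooth(x, signal)$lambda)
  })
  expect_true(all(lambdas["noise", ] > lambdas["signal", ]))
})

test_that("noise-free sexwise trends back-transform to the generator truth", {
  cfg <- cohort_config(n_subjects = 600, noise_sd = 0, factor_sd = 0,
                       delta_cluster = rep(0, 45), seed = 64)
  co <- simulate_cohort(config = cfg)
  fits <- fit_sexwise_trends(co)
  grid <- seq(25, 85, by = 5)
  for (s in c("M", "F")) {
    curves <- predict_composition_curve(fits, s, grid, n_draws = 200, seed = 1)
    truth_ilr <- nglycoda:::true_mean_ilr(cfg, grid, rep(s, length(grid)),
                                          rep(2L, length(grid)))
    truth <- ilr_inverse(truth_ilr)
    est <- matrix(curves$mean, nrow = length(grid))
    expect_lt(max(abs(est - truth)), 0.5)
    closure <- tapply(curves$mean, curves$age, sum)
    expect_true(all(abs(closure - 100) < 0.1))
  }
})

test_that("composition bands widen monotonically with generator noise", {
  widths <- sapply(c(0.1, 0.3, 0.6), function(sd) {
    co <- simulate_cohort(config = cohort_config(
      n_subjects = 400, noise_sd = sd, factor_sd = 0,
      delta_cluster = rep(0, 45), seed = 65))
    fits <- fit_sexwise_trends(co)
    cv <- predict_composition_curve(fits, "F", seq(30, 80, by = 10),
                                    n_draws = 300, seed = 2)
    mean(cv$upper95 - cv$lower95)
  })
  expect_true(all(diff(widths) > 0))
})

test_that("sex-difference windows find injected divergence and respect symmetry", {
  trends <- nglycoda:::default_age_trends()
  trends$lin[20, "F"] <- 0.45   # strong female-only drift on coordinate 20
  cfg <- cohort_config(n_subjects = 1500, delta_cluster = rep(0, 45),
                       factor_sd = 0, age_trends = trends, seed = 66)
  co <- simulate_cohort(config = cfg)
  fits <- fit_sexwise_trends(co)
  w <- sex_difference_windows(fits, "z20")
  expect_gt(nrow(w), 0)
  expect_gt(max(w$end), 70)     # divergence largest at old ages

  # swapping sex labels reflects the difference curve: identical windows
  co2 <- co
  co2$sex <- ifelse(co$sex == "M", "F", "M")
  fits2 <- fit_sexwise_trends(co2)
  w2 <- sex_difference_windows(fits2, "z20")
  expect_equal(w, w2, tolerance = 1e-8)
})

test_that("null sex-difference windows stay near the pointwise error rate", {
  # identical male/female trends: windows should cover little of the grid
  cover <- sapply(1:5, function(s) {
    cfg <- cohort_config(n_subjects = 700, delta_cluster = rep(0, 45),
                         factor_sd = 0,
                         age_trends = list(
                           sin_amp = matrix(0, 45, 2, dimnames = list(NULL, c("M", "F"))),
                           lin = matrix(0, 45, 2, dimnames = list(NULL, c("M", "F")))),
                         seed = 80 + s)
    co <- simulate_cohort(config = cfg)
    fits <- fit_sexwise_trends(co)
    grid <- seq(20, 89, length.out = 100)
    w <- sex_difference_windows(fits, "z5", age_grid = grid)
    if (nrow(w) == 0) 0 else sum(w$end - w$start) / diff(range(grid))
  })
  expect_lte(mean(cover), 0.10)
})
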