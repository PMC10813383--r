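# Robust PCA, K-means in ilr space, elbow selection and cluster phenotyping.

test_that("robust PCA with h = 1 equals classical PCA", {
  withr::with_seed(101, m <- matrix(rnorm(300 * 10), 300, 10))
  rp <- robust_pca(m, h_fraction = 1)
  ee <- eigen(cov(m), symmetric = TRUE)
  expect_equal(rp$eigenvalues, pmax(ee$values, 0), tolerance = 1e-10)
  expect_true(all(diff(rp$eigenvalues) <= 1e-12))
  expect_equal(unname(crossprod(rp$loadings)), diag(10), tolerance = 1e-8)
  expect_equal(sum(rp$explained_fraction), 1, tolerance = 1e-12)
})

test_that("MCD-based PCA resists gross contamination", {
  withr::with_seed(102, {
    clean <- matrix(rnorm(450 * 6), 450, 6) %*% diag(sqrt(c(6, 3, 1, 0.5, 0.3, 0.1)))
    outliers <- matrix(rnorm(50 * 6, mean = 12), 50, 6)
  })
  ref <- eigen(cov(clean), symmetric = TRUE)$values
  contaminated <- rbind(clean, outliers)
  rob <- robust_pca(contaminated, h_fraction = 0.75, seed = 5)$eigenvalues
  cls <- eigen(cov(contaminated), symmetric = TRUE)$values
  dev_rob <- sum(abs(rob - ref))
  dev_cls <- sum(abs(cls - ref))
  expect_lt(dev_rob, dev_cls / 2)
})

test_that("small samples fall back to classical PCA with a warning", {
  withr::with_seed(103, m <- matrix(rnorm(60 * 5), 60, 5))
  expect_warning(rp <- robust_pca(m, h_fraction = 0.75), "classical")
  expect_equal(rp$method, "classical")
})

test_that("K-means separates clear blobs and orients labels reproducibly", {
  withr::with_seed(104, {
    z1 <- matrix(rnorm(60 * 45, sd = 0.2), 60, 45)
    z1[, 1:11] <- z1[, 1:11] + 2          # simple-glycan-rich blob
    z2 <- matrix(rnorm(90 * 45, sd = 0.2), 90, 45)
  })
  z <- rbind(z1, z2)
  truth <- rep(c(1, 2), c(60, 90))
  km <- kmeans_ilr(z, k = 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(km$labels, truth), 1)
  # orientation: label 1 holds the higher GP1-11 centroid mass
  expect_gt(sum(km$centroid_composition[1, 1:11]),
            sum(km$centroid_composition[2, 1:11]))
  km2 <- kmeans_ilr(z, k = 2, seed = 999)
  expect_equal(km$labels, km2$labels)     # orientation rule beats seed

  km1 <- kmeans_ilr(z, k = 1, seed = 1)
  expect_equal(km1$wss, sum(scale(z, scale = FALSE)^2), tolerance = 1e-8)
})

test_that("the elbow rule picks the curvature maximum and flags linear decline", {
  sel <- select_elbow(c(100, 40, 35, 33, 32))
  expect_equal(sel$chosen_k, 2)           # second differences 55, 3, 1
  expect_false(sel$no_clear_elbow)
  lin <- select_elbow(seq(100, 40, length.out = 7))
  expect_true(lin$no_clear_elbow)
})

test_that("WSS decreases in k on real cohort coordinates", {
  co <- simulate_cohort(n_subjects = 300, seed = 105)
  el <- choose_k_elbow(co, k_max = 5, n_init = 5, seed = 3)
  expect_true(all(diff(el$wss_curve$wss) < 0))
})

test_that("cluster characterization reproduces the expected trait directions", {
  co <- simulate_cohort(n_subjects = 800, seed = 106)
  ch <- characterize_clusters(co, co$true_cluster)
  tt <- ch$traits
  up_in_1 <- c("G0", "A1", "S0", "OM", "CF")
  down_in_1 <- c("G2", "G3", "S2", "S3", "OF")
  for (tr in up_in_1) {
    expect_gt(tt$median_c1[tt$trait == tr], tt$median_c2[tt$trait == tr])
  }
  for (tr in down_in_1) {
    expect_lt(tt$median_c1[tt$trait == tr], tt$median_c2[tt$trait == tr])
  }
  # swapping labels swaps the summary columns exactly
  ch2 <- characterize_clusters(co, 3 - co$true_cluster)
  expect_equal(ch$traits$median_c1, ch2$traits$median_c2)
  expect_equal(ch$traits$q25_c1, ch2$traits$q25_c2)
  expect_equal(ch$traits$p_value, ch2$traits$p_value)
  # covariate table carries both continuous and categorical rows
  expect_true("fructosamine" %in% ch$covariates$covariate)
  expect_true("smoking" %in% ch$covariates$covariate)
})

test_that("random labels yield few significant phenotype rows", {
  hits <- sapply(1:10, function(s) {
    co <- simulate_cohort(n_subjects = 300, delta_cluster = rep(0, 45),
                          seed = 200 + s)
    withr::with_seed(s, labels <- sample(1:2, 300, replace = TRUE))
    ch <- characterize_clusters(co, labels)
    mean(ch$traits$p_adj < 0.05)
  })
  expect_lte(mean(hits), 0.05)
})

test_that("adjusted models have near-nominal coverage for a null outcome", {
  covered <- sapply(1:100, function(s) {
    withr::with_seed(300 + s, {
      d <- tibble::tibble(age = runif(150, 18, 91),
                          sex = sample(c("M", "F"), 150, TRUE),
                          noise_outcome = rnorm(150))
      labels <- sample(1:2, 150, replace = TRUE)
    })
    m <- adjusted_outcome_models(d, labels, outcomes = "noise_outcome")
    m$lower95 <= 0 && 0 <= m$upper95
  })
  expect_gt(mean(covered), 0.88)
  expect_lt(mean(covered), 1)
})
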