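# Robust PCA on the ilr coordinates, K-means clustering with elbow
# selection, and cluster phenotyping: trait/covariate summary tables and
# covariate-adjusted outcome models.

#' Robust principal component analysis of ilr coordinates
#'
#' Estimates a robust location and scatter of the 45 ilr coordinates by the
#' minimum covariance determinant (MCD): the subset of `h = h_fraction * n`
#' subjects whose covariance has the smallest determinant, found by the
#' FAST-MCD search, followed by a reweighting step that recomputes the
#' estimate from all points within the chi-square 0.975 Mahalanobis cutoff.
#' Principal components are the eigenvectors of the robust scatter; loadings
#' are also mapped to the 46-part clr scale for interpretation in terms of
#' peaks.  With `h_fraction = 1` the analysis is classical PCA.
#'
#' @param x Cohort data frame with GP columns, a composition matrix, or an
#'   ilr matrix (45 columns).
#' @param h_fraction Subset fraction in (0.5, 1]; default 0.75.
#' @param k_components Number of components to retain (default all 45).
#' @param seed Integer seed for the MCD subset search.
#' @return A `robust_pca` object with `eigenvalues`, `loadings` (ilr),
#'   `clr_loadings`, `scores`, `location`, `explained_fraction` and the
#'   weight vector of the reweighting step.
#' @export
robust_pca <- function(x, h_fraction = 0.75, k_components = NULL, seed = 1) {
  m <- cohort_ilr(x)
  n <- nrow(m); p <- ncol(m)
  if (h_fraction <= 0.5 || h_fraction > 1) abort("h_fraction must be in (0.5, 1]")
  classical <- h_fraction == 1
  if (n < 100 && !classical) {
    warn("fewer than 100 subjects: falling back to classical PCA")
    classical <- TRUE
  }
  if (classical) {
    center <- colMeans(m)
    scatter <- stats::cov(m)
    weights <- rep(TRUE, n)
    method <- "classical"
  } else {
    old <- .Random.seed_save(seed)
    on.exit(.Random.seed_restore(old))
    h <- floor(h_fraction * n)
    raw <- MASS::cov.rob(m, method = "mcd", quantile.used = h, nsamp = 500)
    d2 <- stats::mahalanobis(m, raw$center, raw$cov)
    weights <- d2 <= stats::qchisq(0.975, p)
    center <- colMeans(m[weights, , drop = FALSE])
    scatter <- stats::cov(m[weights, , drop = FALSE])
    method <- "mcd"
  }
  ee <- eigen(scatter, symmetric = TRUE)
  if (any(ee$values < -1e-8)) abort("singular scatter matrix")
  ev <- pmax(ee$values, 0)
  k <- k_components %||% p
  load_k <- ee$vectors[, seq_len(k), drop = FALSE]
  colnames(load_k) <- paste0("PC", seq_len(k))
  scores <- sweep(m, 2, center) %*% load_k
  structure(list(
    eigenvalues = ev,
    loadings = load_k,
    clr_loadings = ilr_basis(p + 1) %*% load_k,
    scores = scores,
    location = center,
    explained_fraction = ev / sum(ev),
    weights = weights,
    method = method,
    h_fraction = h_fraction,
    n = n), class = "robust_pca")
}

#' @export
print.robust_pca <- function(x, ...) {
  cat(sprintf("Robust PCA (%s), n = %d\n", x$method, x$n))
  ef <- x$explained_fraction
  cat(sprintf("  explained: PC1 %.1f%%, PC2 %.1f%%, PC1+PC2 %.1f%%\n",
              100 * ef[1], 100 * ef[2], 100 * sum(ef[1:2])))
  invisible(x)
}

#' K-means clustering in ilr space
#'
#' Runs K-means (best of `n_init` starts) on the 45 ilr coordinates, where
#' Euclidean distance equals the Aitchison distance on the simplex.  Cluster
#' labels are oriented reproducibly: label 1 is the cluster whose centroid
#' carries the highest total abundance of the simple-glycan peaks GP1-GP11,
#' and remaining clusters follow in decreasing order of that measure.
#'
#' @param x Cohort data frame, composition matrix, or ilr matrix.
#' @param k Number of clusters.
#' @param n_init Number of random starts (default 25).
#' @param seed Integer seed.
#' @return A `glyco_kmeans` object with `labels`, ilr `centroids`,
#'   `centroid_composition` (percent), `wss` (total within-cluster sum of
#'   squares), `totss`, `k` and `sizes`.
#' @export
kmeans_ilr <- function(x, k, n_init = 25, seed = 1) {
  m <- cohort_ilr(x)
  if (k < 1 || k >= nrow(m)) abort("k must be in [1, n)")
  old <- .Random.seed_save(seed)
  on.exit(.Random.seed_restore(old))
  km <- suppressWarnings(
    stats::kmeans(m, centers = k, nstart = n_init, iter.max = 100))
  comp <- ilr_inverse(km$centers)
  simple_mass <- if (k == 1) 0 else rowSums(comp[, 1:11, drop = FALSE])
  ord <- order(simple_mass, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  structure(list(
    labels = relabel[km$cluster],
    centroids = km$centers[ord, , drop = FALSE],
    centroid_composition = comp[ord, , drop = FALSE],
    wss = sum(km$withinss),
    totss = km$totss,
    sizes = km$size[ord],
    k = k, seed = seed), class = "glyco_kmeans")
}

#' @export
print.glyco_kmeans <- function(x, ...) {
  cat(sprintf("K-means in ilr space: k = %d, sizes = %s, WSS = %.1f\n",
              x$k, paste(x$sizes, collapse = "/"), x$wss))
  invisible(x)
}

#' Elbow scan for the number of clusters
#'
#' Computes the within-cluster sum of squares for `k = 1..k_max` and selects
#' the elbow as the `k` in `2..k_max-1` maximizing the normalized second
#' difference `(WSS[k-1] - 2 WSS[k] + WSS[k+1]) / WSS[1]`.  When the largest
#' normalized second difference is below 0.01 the WSS decline is essentially
#' linear and the result is flagged as having no clear elbow.
#'
#' @param x Cohort data frame, composition matrix, or ilr matrix.
#' @param k_max Largest k scanned (at least 3; default 8).
#' @param n_init,seed Passed to [kmeans_ilr()].
#' @return An `elbow_scan` object: `wss_curve` tibble (`k`, `wss`),
#'   `chosen_k`, `no_clear_elbow` flag, and the fitted `glyco_kmeans` for the
#'   chosen k.
#' @export
choose_k_elbow <- function(x, k_max = 8, n_init = 25, seed = 1) {
  if (k_max < 3) abort("k_max must be at least 3")
  m <- cohort_ilr(x)
  fits <- lapply(seq_len(k_max), function(k) kmeans_ilr(m, k, n_init, seed + k))
  wss <- vapply(fits, `[[`, 0, "wss")
  sel <- select_elbow(wss)
  structure(c(sel, list(
    wss_curve = tibble::tibble(k = seq_len(k_max), wss = wss),
    fit = fits[[sel$chosen_k]])), class = "elbow_scan")
}

#' Elbow rule on a WSS curve
#'
#' Applies the selection rule of [choose_k_elbow()] to an already computed
#' within-cluster sum-of-squares curve: the chosen k maximizes the
#' normalized second difference of WSS over interior k, with a flag when the
#' decline is essentially linear (maximum below 0.01).
#'
#' @param wss Numeric WSS values for `k = 1..k_max` (`k_max >= 3`).
#' @return List with `chosen_k`, `no_clear_elbow` and a
#'   `second_differences` tibble.
#' @export
#' @examples
#' select_elbow(c(100, 40, 35, 33, 32))$chosen_k  # 2
select_elbow <- function(wss) {
  k_max <- length(wss)
  if (k_max < 3) abort("need WSS for at least 3 values of k")
  ks <- 2:(k_max - 1)
  d2 <- (wss[ks - 1] - 2 * wss[ks] + wss[ks + 1]) / wss[1]
  list(chosen_k = ks[which.max(d2)],
       no_clear_elbow = max(d2) < 0.01,
       second_differences = tibble::tibble(k = ks, value = d2))
}

#' @export
print.elbow_scan <- function(x, ...) {
  cat(sprintf("Elbow scan over k = 1..%d: chosen k = %d%s\n",
              max(x$wss_curve$k), x$chosen_k,
              if (x$no_clear_elbow) " (no clear elbow)" else ""))
  invisible(x)
}

cluster_summary_num <- function(v, labels) {
  tibble::tibble(cluster = sort(unique(labels))) |>
    dplyr::mutate(
      median = vapply(.data$cluster, function(g) stats::median(v[labels == g], na.rm = TRUE), 0),
      q25 = vapply(.data$cluster, function(g) unname(stats::quantile(v[labels == g], 0.25, na.rm = TRUE)), 0),
      q75 = vapply(.data$cluster, function(g) unname(stats::quantile(v[labels == g], 0.75, na.rm = TRUE)), 0))
}

test_num_by_cluster <- function(v, labels) {
  groups <- split(v[!is.na(v)], labels[!is.na(v)])
  if (length(groups) == 2) mann_whitney(groups[[1]], groups[[2]])
  else kruskal_wallis(groups)
}

#' Phenotype clusters by traits and covariates
#'
#' Summarizes the derived glycosylation traits and the clinical covariates
#' per cluster and tests for differences: Mann-Whitney (two clusters) or
#' Kruskal-Wallis (more) for continuous variables, Pearson chi-square for
#' categorical ones, with Benjamini-Hochberg adjustment within each table.
#' Rank tests are invariant to monotone per-variable transforms, so testing
#' trait percentages is equivalent to testing their logit or log-ratio
#' rescalings.
#'
#' @param data Cohort data frame with GP columns and optional covariates.
#' @param labels Integer cluster labels, one per row of `data`.
#' @param covariates Covariate column names to summarize; defaults to every
#'   column that is not a peak, ilr coordinate, subject id or generator
#'   ground-truth column.
#' @return List with `traits` and `covariates` tibbles: per-cluster medians
#'   and IQRs (or counts and percentages), raw and BH-adjusted p-values.
#' @export
characterize_clusters <- function(data, labels, covariates = NULL) {
  stopifnot(nrow(data) == length(labels))
  if (length(unique(labels)) < 2) abort("need at least two clusters")
  traits <- derive_traits(data, keep = FALSE)
  trait_tab <- purrr::map_dfr(names(traits), function(tr) {
    v <- traits[[tr]]
    s <- cluster_summary_num(v, labels) |>
      tidyr::pivot_wider(names_from = "cluster",
                         values_from = c("median", "q25", "q75"),
                         names_glue = "{.value}_c{cluster}")
    dplyr::bind_cols(tibble::tibble(trait = tr), s,
                     test_num_by_cluster(v, labels)[, c("statistic", "p_value", "method")])
  })
  trait_tab$p_adj <- bh_adjust(trait_tab$p_value)

  if (is.null(covariates)) {
    drop_pat <- "^(GP[0-9]+|z[0-9]+|subject_id|true_)"
    covariates <- setdiff(names(data)[!grepl(drop_pat, names(data))], character())
  }
  cov_tab <- purrr::map_dfr(covariates, function(cv) {
    v <- data[[cv]]
    if (length(unique(v[!is.na(v)])) < 2) {
      inform(paste0("covariate ", cv, " has a single value; skipped"))
      return(NULL)
    }
    if (is.numeric(v)) {
      s <- cluster_summary_num(v, labels) |>
        tidyr::pivot_wider(names_from = "cluster",
                           values_from = c("median", "q25", "q75"),
                           names_glue = "{.value}_c{cluster}")
      dplyr::bind_cols(tibble::tibble(covariate = cv, level = NA_character_), s,
                       test_num_by_cluster(v, labels)[, c("statistic", "p_value", "method")])
    } else {
      tab <- table(factor(v), labels)
      ct <- chi_square(tab)
      pct <- prop.table(tab, margin = 2) * 100
      purrr::map_dfr(rownames(tab), function(lv) {
        row <- tibble::tibble(covariate = cv, level = lv)
        for (g in colnames(tab)) {
          row[[paste0("n_c", g)]] <- unname(tab[lv, g])
          row[[paste0("pct_c", g)]] <- unname(pct[lv, g])
        }
        row$statistic <- ct$statistic; row$p_value <- ct$p_value
        row$method <- ct$method
        row
      })
    }
  })
  if (nrow(cov_tab) > 0) {
    # one p per covariate; adjust on unique covariates, broadcast to levels
    pmap <- cov_tab |> dplyr::distinct(.data$covariate, .data$p_value)
    pmap$p_adj <- bh_adjust(pmap$p_value)
    cov_tab <- dplyr::left_join(cov_tab, pmap[, c("covariate", "p_adj")],
                                by = "covariate")
  }
  list(traits = trait_tab, covariates = cov_tab)
}

#' Age- and sex-adjusted cluster effects on outcomes
#'
#' For each outcome, fits `outcome ~ cluster1 + age + sex`: linear regression
#' for continuous outcomes (reporting the cluster-1 mean difference with a
#' 95% Wald interval) and logistic regression for binary outcomes (reporting
#' the odds ratio).  Coefficients beyond 15 in absolute value on the logit
#' scale are flagged as separation and their intervals suppressed.
#'
#' @param data Cohort data frame with `age`, `sex` and outcome columns.
#' @param labels Cluster labels; cluster 1 is the exposure of interest.
#' @param outcomes Character vector of outcome column names; defaults to all
#'   numeric covariate columns (non-peak, non-coordinate, not age) plus a
#'   derived `comorbidity_ge2` indicator when `comorbidity_count` is present.
#' @return Tibble with `outcome`, `type` (`"linear"`/`"logistic"`),
#'   `estimate` (difference or odds ratio), `lower95`, `upper95`, `p_value`,
#'   `separation`.
#' @export
adjusted_outcome_models <- function(data, labels, outcomes = NULL) {
  stopifnot(nrow(data) == length(labels))
  d <- tibble::as_tibble(data)
  d$cluster1 <- as.integer(labels == 1)
  if ("comorbidity_count" %in% names(d) && !("comorbidity_ge2" %in% names(d))) {
    d$comorbidity_ge2 <- as.integer(d$comorbidity_count >= 2)
  }
  if (is.null(outcomes)) {
    drop_pat <- "^(GP[0-9]+|z[0-9]+|subject_id|true_|cluster1$|age$|sex$)"
    outcomes <- names(d)[!grepl(drop_pat, names(d))]
    outcomes <- outcomes[vapply(d[outcomes], is.numeric, TRUE)]
    outcomes <- setdiff(outcomes, "comorbidity_count")
  }
  purrr::map_dfr(outcomes, function(oc) {
    if (!oc %in% names(d)) abort(paste0("unknown outcome: ", oc))
    y <- d[[oc]]
    binary <- length(unique(y[!is.na(y)])) == 2 && all(y %in% c(0, 1, NA))
    fml <- stats::as.formula(paste0("`", oc, "` ~ cluster1 + age + sex"))
    if (binary) {
      fit <- stats::glm(fml, data = d, family = stats::binomial())
      co <- unname(summary(fit)$coefficients["cluster1", ])
      sep <- abs(co[1]) > 15
      tibble::tibble(outcome = oc, type = "logistic",
                     estimate = exp(co[1]),
                     lower95 = if (sep) NA_real_ else exp(co[1] - 1.96 * co[2]),
                     upper95 = if (sep) NA_real_ else exp(co[1] + 1.96 * co[2]),
                     p_value = co[4], separation = sep)
    } else {
      fit <- stats::lm(fml, data = d)
      co <- unname(summary(fit)$coefficients["cluster1", ])
      tibble::tibble(outcome = oc, type = "linear",
                     estimate = co[1],
                     lower95 = co[1] - 1.96 * co[2],
                     upper95 = co[1] + 1.96 * co[2],
                     p_value = co[4], separation = FALSE)
    }
  })
}

#' One-call clustering of a cohort
#'
#' Convenience wrapper running the elbow scan, K-means at the chosen k, and
#' cluster phenotyping in one step.
#'
#' @param data Cohort data frame.
#' @param k_max,n_init,seed Passed to [choose_k_elbow()].
#' @return List with `elbow`, `kmeans`, `characterization` and
#'   `adjusted_models`.
#' @export
cluster_glycome <- function(data, k_max = 8, n_init = 25, seed = 1) {
  elbow <- choose_k_elbow(data, k_max, n_init, seed)
  km <- elbow$fit
  list(elbow = elbow, kmeans = km,
       characterization = characterize_clusters(data, km$labels),
       adjusted_models = adjusted_outcome_models(data, km$labels))
}
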