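# End-to-end pipeline driver: simulate or load a cohort, transform, test,
# fit trends, run PCA and clustering, phenotype the clusters, and write
# per-stage TSV outputs plus a run log.

#' Run the full glycome analysis pipeline
#'
#' Executes the analysis stages in order -- cohort (simulate or load), zero
#' replacement and ilr transform, derived traits, male/female comparison
#' (global permutation test plus per-coordinate follow-up), per-sex age
#' trends, robust PCA, elbow-selected K-means, cluster phenotyping and
#' adjusted outcome models -- under one master seed, optionally writing each
#' stage's table as TSV together with a plain-text run log.
#'
#' @param config Either a `glyco_config` (the cohort is simulated), a path
#'   to a YAML config file, or a cohort data frame / CSV path to analyse
#'   as-is.
#' @param out_dir Optional output directory for TSVs and the run log.
#' @param seed Master seed for every stochastic stage (default 1).
#' @param stages Character subset of
#'   `c("traits", "sex_tests", "trends", "pca", "clusters")`; default all.
#' @param age_grid Ages for the trend curves (default 20 points over the
#'   cohort range).
#' @param trait_trends Optional character vector of bounded-trait names
#'   (e.g. `"CF"`, `"OF"`, `"OM"`) to model with per-sex beta-response
#'   smooths; unknown names raise an error naming the trait.
#' @return A named list (`report bundle`) with the cohort, per-stage results
#'   and the log lines.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL, seed = 1,
                         stages = c("traits", "sex_tests", "trends", "pca",
                                    "clusters"),
                         age_grid = NULL, trait_trends = NULL) {
  log_lines <- c(paste0("nglycoda ", as.character(utils::packageVersion("nglycoda"))),
                 paste0("R ", R.version.string),
                 paste0("seed ", seed))
  stage <- "cohort"
  bundle <- list()
  run <- function(expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }
  cohort <- run({
    if (is.character(config) && grepl("\\.ya?ml$", config)) config <- read_config(config)
    if (is.character(config)) config <- read_cohort(config)
    if (inherits(config, "glyco_config")) {
      config$seed <- as.integer(seed)
      log_lines <<- c(log_lines, paste0("config hash ", rlang::hash(unclass(config))))
      simulate_cohort(config = config)
    } else {
      tibble::as_tibble(config)
    }
  })
  bundle$cohort <- cohort

  stage <- "transform"
  ilr_mat <- run(cohort_ilr(cohort))
  bundle$ilr <- ilr_mat

  if ("traits" %in% stages) {
    stage <- "traits"
    bundle$traits <- run(derive_traits(cohort, keep = FALSE))
  }
  if ("sex_tests" %in% stages && "sex" %in% names(cohort)) {
    stage <- "sex_tests"
    bundle$sex_global <- run(global_composition_test(
      cohort[cohort$sex == "M", ], cohort[cohort$sex == "F", ],
      n_perm = 999, seed = seed))
    bundle$sex_peakwise <- run(peakwise_comparison(
      cohort[cohort$sex == "M", ], cohort[cohort$sex == "F", ]))
  }
  if ("trends" %in% stages && all(c("sex", "age") %in% names(cohort))) {
    stage <- "trends"
    bundle$trend_fits <- run(fit_sexwise_trends(cohort))
    grid <- age_grid %||% seq(min(cohort$age), max(cohort$age), length.out = 20)
    bundle$trend_curves <- run(dplyr::bind_rows(
      predict_composition_curve(bundle$trend_fits, "M", grid, seed = seed),
      predict_composition_curve(bundle$trend_fits, "F", grid, seed = seed + 1)))
  }
  if (!is.null(trait_trends)) {
    stage <- "trait_trends"
    traits_all <- derive_traits(cohort, keep = FALSE)
    bundle$trait_trend_fits <- run({
      unknown <- setdiff(trait_trends, names(traits_all))
      if (length(unknown) > 0) abort(paste0("unknown trait: ", unknown[1]))
      lapply(setNames(trait_trends, trait_trends), function(tr) {
        fit_beta_smooth(cohort$age, traits_all[[tr]] / 100, sex = cohort$sex)
      })
    })
  }
  if ("pca" %in% stages) {
    stage <- "pca"
    bundle$pca <- run(robust_pca(ilr_mat, seed = seed))
  }
  if ("clusters" %in% stages) {
    stage <- "clusters"
    bundle$elbow <- run(choose_k_elbow(ilr_mat, seed = seed))
    bundle$kmeans <- bundle$elbow$fit
    bundle$characterization <- run(
      characterize_clusters(cohort, bundle$kmeans$labels))
    if (all(c("age", "sex") %in% names(cohort))) {
      bundle$adjusted_models <- run(
        adjusted_outcome_models(cohort, bundle$kmeans$labels))
    }
    log_lines <- c(log_lines, paste0("chosen_k ", bundle$elbow$chosen_k))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, name) {
      if (!is.null(x)) readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
    }
    wr(cohort, "cohort")
    wr(bundle$traits, "traits")
    wr(bundle$sex_peakwise, "sex_peakwise")
    wr(bundle$trend_curves, "trend_curves")
    if (!is.null(bundle$elbow)) {
      wr(bundle$elbow$wss_curve, "elbow_wss")
      wr(bundle$characterization$traits, "cluster_traits")
      wr(bundle$characterization$covariates, "cluster_covariates")
      wr(tibble::tibble(subject = seq_along(bundle$kmeans$labels),
                        cluster = bundle$kmeans$labels), "cluster_labels")
    }
    wr(bundle$adjusted_models, "adjusted_models")
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  bundle$log <- log_lines
  bundle
}
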