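# Synthetic cohort generator.  Emulates the statistical structure the
# analysis assumes: a 46-part glycan composition with two latent clusters
# (simple-glycan-rich vs higher-order-rich), smooth per-sex age trends on the
# ilr scale, a rank-2 latent factor covariance so two principal components
# dominate, and clinical covariates associated with cluster membership.
# Ground truth (labels, deterministic ilr means) is returned for recovery
# tests.

# Baseline serum glycome profile (percent of total area, before closure):
# dominated by biantennary digalactosylated sialylated structures in the
# middle of the spectrum, with modest simple glycans early and minor
# high-order peaks late.
BASE_PROFILE <- c(
  1.5, 2.0, 0.8, 2.5, 1.2, 1.8, 0.9, 2.2, 1.5, 1.0,   # GP1-10
  0.7, 1.1, 2.0, 5.5, 2.5, 1.8, 1.2, 1.5, 1.0, 1.6,   # GP11-20
  1.3, 1.4, 1.1, 8.0, 6.5, 12.0, 2.2, 1.6, 2.4, 1.0,  # GP21-30
  1.8, 2.8, 3.5, 2.0, 1.5, 1.2, 1.4, 1.9, 1.1, 2.3,   # GP31-40
  1.6, 1.2, 1.9, 0.9, 0.8, 0.6)                       # GP41-46

# Default cluster offset on the ilr scale: +1.5 on the first 11 pivot
# coordinates raises the mass of GP1-GP11 (simple glycans) in cluster 1.
default_delta_cluster <- function() {
  c(rep(1.5, 11), rep(0, 34))
}

# Default rank-2 factor loadings: two smooth spectral contrast patterns,
# orthogonalized against the cluster-offset direction (so the continuous
# covariance and the discrete cluster signal are identifiable) and against
# each other, each scaled to norm 2.
default_factor_loadings <- function(delta = default_delta_cluster()) {
  j <- seq_len(45)
  raw <- cbind(cos(pi * (j - 1) / 44), sin(2 * pi * (j - 1) / 44))
  u1 <- raw[, 1]
  if (any(delta != 0)) {
    d <- delta / sqrt(sum(delta^2))
    u1 <- u1 - sum(u1 * d) * d
  } else {
    d <- rep(0, 45)
  }
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- raw[, 2] - sum(raw[, 2] * d) * d - sum(raw[, 2] * u1) * u1
  u2 <- u2 / sqrt(sum(u2^2))
  unname(2 * cbind(u1, u2))
}

# Default smooth age-trend parameters per ilr coordinate and sex:
# trend(age) = sin_amp * sin(pi (age-18)/73) + lin * (age-52)/10.
# Early-spectrum coordinates carry a shared hump; late coordinates 40-45
# drift upward with age in women only (sex-divergent sialylation-like
# pattern).
default_age_trends <- function() {
  sin_amp <- matrix(0, 45, 2, dimnames = list(NULL, c("M", "F")))
  lin <- sin_amp
  sin_amp[1:8, ] <- 0.15
  lin[1:8, ] <- 0.02
  lin[40:45, "F"] <- 0.04
  list(sin_amp = sin_amp, lin = lin)
}

#' Configuration of the synthetic cohort generator
#'
#' Collects and validates all generator parameters.  Defaults reproduce the
#' cohort shape of the motivating study: n = 1516 subjects, 55.3% women,
#' ages uniform on 18-91, a latent simple-glycan-rich cluster with baseline
#' prevalence 431/1516 whose log-odds increase by 0.3 per decade of age, a
#' +14.1 umol/L fructosamine shift and a 1.53 odds ratio of carrying two or
#' more comorbidities in that cluster.
#'
#' @param n_subjects Number of subjects (default 1516).
#' @param p_female Probability of female sex (default 0.553).
#' @param age_range Two ages in years (default `c(18, 91)`), sampled
#'   uniformly.
#' @param cluster_base_logodds Cluster-1 log-odds at the median age of 52
#'   (default `qlogis(431/1516)`).
#' @param cluster_age_slope Increase in cluster-1 log-odds per decade of age
#'   (default 0.3).
#' @param delta_cluster 45-vector of ilr-scale offsets added in cluster 1;
#'   the default raises GP1-GP11 mass.
#' @param factor_loadings 45 x 2 rank-2 loading matrix of the latent factors.
#' @param factor_sd Standard deviation of the two factor scores (default 1).
#' @param noise_sd Independent ilr noise standard deviation (default 0.25).
#' @param age_trends List with 45 x 2 matrices `sin_amp` and `lin` (columns
#'   `M`, `F`) parameterizing the per-coordinate smooth age trends.
#' @param fructosamine_baseline,fructosamine_shift Baseline level and
#'   cluster-1 shift in umol/L (defaults 251 and 14.1).
#' @param comorbidity_log_odds Cluster-1 log-odds shift of the
#'   two-or-more-comorbidities event (default `log(1.53)`).
#' @param seed Integer master seed.
#' @return A validated `glyco_config` list.
#' @export
cohort_config <- function(n_subjects = 1516,
                          p_female = 0.553,
                          age_range = c(18, 91),
                          cluster_base_logodds = stats::qlogis(431 / 1516),
                          cluster_age_slope = 0.3,
                          delta_cluster = default_delta_cluster(),
                          factor_loadings = NULL,
                          factor_sd = 1.0,
                          noise_sd = 0.25,
                          age_trends = default_age_trends(),
                          fructosamine_baseline = 251,
                          fructosamine_shift = 14.1,
                          comorbidity_log_odds = log(1.53),
                          seed = 1L) {
  factor_loadings <- factor_loadings %||% default_factor_loadings(delta_cluster)
  cfg <- list(n_subjects = as.integer(n_subjects), p_female = p_female,
              age_range = as.numeric(age_range),
              cluster_base_logodds = cluster_base_logodds,
              cluster_age_slope = cluster_age_slope,
              delta_cluster = as.numeric(delta_cluster),
              factor_loadings = as.matrix(factor_loadings),
              factor_sd = factor_sd, noise_sd = noise_sd,
              age_trends = age_trends,
              fructosamine_baseline = fructosamine_baseline,
              fructosamine_shift = fructosamine_shift,
              comorbidity_log_odds = comorbidity_log_odds,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "glyco_config")
}

validate_config <- function(cfg) {
  num_fields <- c("p_female", "cluster_base_logodds", "cluster_age_slope",
                  "factor_sd", "noise_sd", "fructosamine_baseline",
                  "fructosamine_shift", "comorbidity_log_odds")
  for (f in num_fields) {
    if (!is.numeric(cfg[[f]]) || any(!is.finite(cfg[[f]]))) {
      abort(paste0("config field ", f, " must be finite"))
    }
  }
  if (cfg$n_subjects < 1) abort("n_subjects must be positive")
  if (cfg$p_female < 0 || cfg$p_female > 1) abort("p_female must lie in [0, 1]")
  if (length(cfg$age_range) != 2 || diff(cfg$age_range) <= 0 ||
      any(!is.finite(cfg$age_range))) {
    abort("age_range must be an increasing pair of finite ages")
  }
  if (length(cfg$delta_cluster) != 45 || any(!is.finite(cfg$delta_cluster))) {
    abort("delta_cluster must be a finite 45-vector")
  }
  if (!all(dim(cfg$factor_loadings) == c(45, 2)) ||
      any(!is.finite(cfg$factor_loadings))) {
    abort("factor_loadings must be a finite 45 x 2 matrix")
  }
  if (qr(cfg$factor_loadings)$rank != 2 &&
      !(cfg$factor_sd == 0)) {
    abort("factor_loadings must have rank 2")
  }
  if (cfg$factor_sd < 0 || cfg$noise_sd < 0) abort("sds must be non-negative")
  invisible(cfg)
}

#' @export
print.glyco_config <- function(x, ...) {
  cat(sprintf("Synthetic glycome cohort config: n = %d, p_female = %.3f, ages %g-%g\n",
              x$n_subjects, x$p_female, x$age_range[1], x$age_range[2]))
  cat(sprintf("  cluster: base log-odds %.3f, slope %.2f/decade, |delta| = %.2f\n",
              x$cluster_base_logodds, x$cluster_age_slope,
              sqrt(sum(x$delta_cluster^2))))
  cat(sprintf("  factor_sd = %g, noise_sd = %g, seed = %d\n",
              x$factor_sd, x$noise_sd, x$seed))
  invisible(x)
}

# One independent stream per variable block: adding a block never perturbs
# draws of earlier blocks.  Sub-seeds stay below 2^31.
with_stream <- function(seed, block, expr) {
  old <- .Random.seed_save(((abs(seed) %% 100000L) * 19937L + block * 101L) %% 2147483647L)
  on.exit(.Random.seed_restore(old))
  force(expr)
}

# deterministic ilr mean: baseline + cluster offset + sex-specific age trend
true_mean_ilr <- function(cfg, age, sex, cluster) {
  n <- length(age)
  beta0 <- ilr_transform(close_composition(BASE_PROFILE))
  mu <- matrix(beta0, n, 45, byrow = TRUE)
  mu <- mu + outer(as.numeric(cluster == 1), cfg$delta_cluster)
  s_hump <- sin(pi * (age - 18) / 73)
  s_lin <- (age - 52) / 10
  for (s in c("M", "F")) {
    rows <- sex == s
    if (!any(rows)) next
    mu[rows, ] <- mu[rows, ] +
      outer(s_hump[rows], cfg$age_trends$sin_amp[, s]) +
      outer(s_lin[rows], cfg$age_trends$lin[, s])
  }
  mu
}

#' Simulate a synthetic glycomics cohort
#'
#' Draws a cohort from the fixed generative model: sex is Bernoulli, age
#' uniform, cluster membership Bernoulli with age-dependent log-odds; each
#' subject's deterministic ilr mean is the baseline glycome plus the cluster
#' offset plus the sex-specific smooth age trend, and observed coordinates
#' add a rank-2 latent factor term and independent Gaussian noise before
#' back-transforming to percentages closed to 100.  Covariates (glucose,
#' fructosamine, glycated albumin, TNF-alpha, AST, GGT, glomerular
#' filtration rate, comorbidity count, smoking) follow documented
#' linear-plus-noise links to age, sex and cluster; comorbidity uses a
#' two-part model so the cluster effect is an exact log-odds shift on the
#' two-or-more event.  The same seed gives bit-identical output.
#'
#' @param ... Arguments forwarded to [cohort_config()].
#' @param config A ready-made `glyco_config` (overrides `...`).
#' @return A `glyco_cohort` tibble with `subject_id`, `sex`, `age`,
#'   `GP1..GP46`, covariates and `true_cluster`; the deterministic ilr means
#'   are in `attr(, "true_ilr_means")` and the config in `attr(, "config")`.
#' @export
#' @examples
#' cohort <- simulate_cohort(n_subjects = 200, seed = 7)
#' range(rowSums(cohort[gp_names()]))
simulate_cohort <- function(..., config = NULL) {
  cfg <- config %||% cohort_config(...)
  validate_config(cfg)
  n <- cfg$n_subjects; seed <- cfg$seed

  sex <- with_stream(seed, 1L, ifelse(stats::runif(n) < cfg$p_female, "F", "M"))
  age <- with_stream(seed, 2L, stats::runif(n, cfg$age_range[1], cfg$age_range[2]))
  lo <- cfg$cluster_base_logodds + cfg$cluster_age_slope * (age - 52) / 10
  cluster <- with_stream(seed, 3L,
                         ifelse(stats::runif(n) < stats::plogis(lo), 1L, 2L))

  mu <- true_mean_ilr(cfg, age, sex, cluster)
  f <- with_stream(seed, 4L,
                   matrix(stats::rnorm(n * 2, sd = cfg$factor_sd), n, 2))
  eps <- with_stream(seed, 5L,
                     matrix(stats::rnorm(n * 45, sd = cfg$noise_sd), n, 45))
  z <- mu + f %*% t(cfg$factor_loadings) + eps
  comp <- ilr_inverse(z)

  i1 <- as.numeric(cluster == 1)
  ac <- age - 52
  fructosamine <- with_stream(seed, 6L,
    cfg$fructosamine_baseline + cfg$fructosamine_shift * i1 + 0.3 * ac +
      stats::rnorm(n, sd = 20))
  comorbidity_count <- with_stream(seed, 7L, {
    p_ge2 <- stats::plogis(-1.8 + 0.04 * ac + cfg$comorbidity_log_odds * i1)
    hi <- stats::runif(n) < p_ge2
    ifelse(hi, 2L + stats::rpois(n, 0.8), stats::rbinom(n, 1L, 0.35))
  })
  glucose <- with_stream(seed, 8L, 91 + 6 * i1 + 0.2 * ac + stats::rnorm(n, sd = 15))
  glycated_albumin <- with_stream(seed, 9L,
    13.6 + 0.58 * i1 + 0.02 * ac + stats::rnorm(n, sd = 1.5))
  ast <- with_stream(seed, 10L, 21 + 0.96 * i1 + stats::rnorm(n, sd = 6))
  ggt <- with_stream(seed, 11L, 25 + 5.34 * i1 + 0.1 * ac + stats::rnorm(n, sd = 15))
  tnf_alpha <- with_stream(seed, 12L,
    7 + 0.03 * ac + 0.5 * (sex == "M") + stats::rnorm(n, sd = 2))
  gfr <- with_stream(seed, 13L, 90 - 0.6 * ac - 3.26 * i1 + stats::rnorm(n, sd = 12))
  smoking <- with_stream(seed, 14L, {
    p_cur <- stats::plogis(-0.8 - 0.03 * ac)
    u <- stats::runif(n)
    ifelse(u < p_cur, "current", ifelse(u < p_cur + 0.25, "former", "never"))
  })

  out <- tibble::tibble(
    subject_id = sprintf("S%05d", seq_len(n)),
    sex = sex, age = age)
  out <- dplyr::bind_cols(out, tibble::as_tibble(comp))
  out$glucose <- glucose
  out$fructosamine <- fructosamine
  out$glycated_albumin <- glycated_albumin
  out$tnf_alpha <- tnf_alpha
  out$ast <- ast
  out$ggt <- ggt
  out$gfr <- gfr
  out$comorbidity_count <- comorbidity_count
  out$smoking <- smoking
  out$true_cluster <- cluster
  attr(out, "true_ilr_means") <- mu
  attr(out, "config") <- cfg
  class(out) <- c("glyco_cohort", class(out))
  out
}
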