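# Cohort table I/O: delimited text with a fixed schema (GP1..GP46 in percent,
# sex coded M/F) plus YAML round-tripping of generator configs.

#' Read a cohort table
#'
#' Reads a comma- or tab-delimited cohort file with a header row, validates
#' the schema (all 46 GP columns present and numeric, unique subject ids,
#' ages within 18-120) and closes each GP row to 100, warning when a raw row
#' sum deviates from 100 by more than half a percentage point.
#'
#' @param path File path; the delimiter is inferred from the header line.
#' @return A tibble with validated GP columns closed to 100.  The number of
#'   rows whose raw sum deviated by more than 1% is stored in
#'   `attr(, "closure_warnings")`.
#' @export
read_cohort <- function(path) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  d <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  missing <- setdiff(GP_NAMES, names(d))
  if (length(missing) > 0) abort(paste0("missing glycan peak column: ", missing[1]))
  for (gp in GP_NAMES) {
    if (!is.numeric(d[[gp]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[gp]]))) & !is.na(d[[gp]]))
      abort(paste0("non-numeric value in column ", gp,
                   if (length(bad)) paste0(", row ", bad[1]) else ""))
    }
  }
  if ("subject_id" %in% names(d) && anyDuplicated(d$subject_id)) {
    abort(paste0("duplicate subject_id: ",
                 d$subject_id[anyDuplicated(d$subject_id)][1]))
  }
  if ("age" %in% names(d) && any(d$age < 18 | d$age > 120, na.rm = TRUE)) {
    abort("age outside [18, 120]")
  }
  m <- as_gp_matrix(d)
  raw_sums <- rowSums(m)
  n_off <- sum(abs(raw_sums - 100) > 0.5)
  if (n_off > 0) {
    warn(paste0(n_off, " row(s) with raw GP sum deviating from 100% by more ",
                "than 0.5; closed to 100"))
  }
  d[, GP_NAMES] <- tibble::as_tibble(close_composition(m))
  attr(d, "closure_warnings") <- n_off
  d
}

#' Write a cohort table
#'
#' @param data Cohort data frame.
#' @param path Output path; `.tsv` extension selects tab, anything else
#'   comma.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  if (grepl("\\.tsv$", path)) readr::write_tsv(data, path)
  else readr::write_csv(data, path)
  invisible(path)
}

#' Serialize a generator config as YAML
#'
#' @param config A `glyco_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$factor_loadings <- as.vector(x$factor_loadings)
  x$age_trends <- lapply(x$age_trends, as.vector)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a generator config from YAML
#'
#' @param path YAML file written by [write_config()]; missing fields take
#'   their defaults.
#' @return A validated `glyco_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$factor_loadings)) {
    x$factor_loadings <- matrix(as.numeric(x$factor_loadings), 45, 2)
  }
  if (!is.null(x$age_trends)) {
    x$age_trends <- lapply(x$age_trends, function(v) {
      matrix(as.numeric(v), 45, 2, dimnames = list(NULL, c("M", "F")))
    })
  }
  do.call(cohort_config, x)
}
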