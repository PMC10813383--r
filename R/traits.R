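# Derived glycosylation traits: weighted sums of the 46 peaks grouped by a
# shared structural feature.  Peaks whose glycans carry two features split
# their area evenly (weights 1/2 or 1/3), so the sialylation weights tile all
# 46 peaks exactly once, as do galactosylation+oligomannose and
# branching+oligomannose.  Stored as integer numerator/denominator pairs so
# that G3/A3 and G4/A4 (identical peak sets) are computed bit-identically.

TRAIT_NAMES <- c("G0", "G1", "G2", "G3", "G4",
                 "S0", "S1", "S2", "S3", "S4",
                 "A1", "A2", "A3", "A4",
                 "CF", "OF", "OM")

trait_def <- local({
  w <- function(peaks, den = 1L) {
    tibble::tibble(peak = as.integer(peaks), num = 1L, den = as.integer(den))
  }
  high_order <- list(  # shared by galactosylation and branching
    P3 = dplyr::bind_rows(w(29), w(31:37)),
    P4 = dplyr::bind_rows(w(30), w(38:46)))
  list(
    G0 = dplyr::bind_rows(w(c(1, 2, 4, 5)), w(6, 2), w(12, 2)),
    G1 = dplyr::bind_rows(w(3), w(7:10), w(12, 2), w(16:18), w(21, 2)),
    G2 = dplyr::bind_rows(w(13:15), w(19:20), w(21, 2), w(22:28)),
    G3 = high_order$P3,
    G4 = high_order$P4,
    S0 = w(1:15),
    S1 = dplyr::bind_rows(w(16:23), w(30)),
    S2 = dplyr::bind_rows(w(24:29), w(31)),
    S3 = w(32:40),
    S4 = w(41:46),
    A1 = dplyr::bind_rows(w(1:3), w(12, 2), w(21, 2)),
    A2 = dplyr::bind_rows(w(4:5), w(6, 2), w(7:10), w(12, 2), w(13:20),
                          w(21, 2), w(22:28)),
    A3 = high_order$P3,
    A4 = high_order$P4,
    CF = dplyr::bind_rows(w(c(2, 5)), w(6, 2), w(8:10), w(14:15), w(17:18),
                          w(22:23), w(27:28), w(36), w(44, 2)),
    OF = dplyr::bind_rows(w(c(37, 40)), w(41, 3), w(45), w(46, 3)),
    OM = dplyr::bind_rows(w(6, 2), w(11))
  )
})

#' Derived-trait weight map
#'
#' The mapping from the 46 glycan peaks to the 17 derived traits:
#' galactosylation `G0`--`G4`, sialylation `S0`--`S4`, branching
#' (antennarity) `A1`--`A4`, core fucose `CF`, outer-arm fucose `OF` and
#' oligomannose `OM`.  Peaks carrying two features contribute fractional
#' weight (1/2 or 1/3) to each.  `G3`/`A3` and `G4`/`A4` share identical peak
#' sets, so those trait pairs are numerically identical by construction.
#'
#' @return A tibble with columns `trait`, `peak` (e.g. `"GP6"`), and
#'   `weight` in `{1, 1/2, 1/3}`.
#' @export
#' @examples
#' dplyr::filter(trait_weights(), peak == "GP6")
trait_weights <- function() {
  purrr::imap_dfr(trait_def, function(d, nm) {
    tibble::tibble(trait = nm, peak = paste0("GP", d$peak),
                   weight = d$num / d$den)
  })
}

# 46 x 17 weight matrix, columns in TRAIT_NAMES order
trait_weight_matrix <- function() {
  W <- matrix(0, N_PEAKS, length(TRAIT_NAMES),
              dimnames = list(GP_NAMES, TRAIT_NAMES))
  for (nm in TRAIT_NAMES) {
    d <- trait_def[[nm]]
    W[d$peak, nm] <- d$num / d$den
  }
  W
}

#' Compute derived glycosylation traits
#'
#' Applies the [trait_weights()] map row-wise: each trait is the weighted sum
#' of the (closed, percent-scale) peak abundances in its group, so traits are
#' themselves percentages of total glycan area.  For every subject the
#' sialylation traits sum to 100, as do galactosylation plus oligomannose and
#' branching plus oligomannose.
#'
#' @param x Data frame with `GP1..GP46` columns, a composition matrix, or a
#'   single composition vector.
#' @param keep For data frame input, whether to bind the trait columns to the
#'   input columns (default) or return the traits alone.
#' @return A tibble with one row per subject and columns `G0..OM` (a named
#'   vector for vector input).
#' @export
#' @examples
#' x <- close_composition(stats::setNames(rep(1, 46), gp_names()))
#' derive_traits(x)[["S3"]]  # 9 peaks * 100/46
derive_traits <- function(x, keep = TRUE) {
  if (is.data.frame(x)) {
    tr <- tibble::as_tibble(as_gp_matrix(x) %*% trait_weight_matrix())
    return(if (keep) dplyr::bind_cols(x, tr) else tr)
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  out <- m %*% trait_weight_matrix()
  if (vec) out[1, ] else out
}
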