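#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats setNames
NULL

# Canonical peak names, fixed order. The pivot ilr basis and the simple-vs-
# complex interpretation of the first coordinates both depend on this order.
GP_NAMES <- paste0("GP", 1:46)
N_PEAKS  <- 46L

#' Glycan peak column names
#'
#' The 46 chromatographic glycan peak columns, `GP1` to `GP46`, in the fixed
#' elution order that defines the pivot ilr basis used throughout the package.
#'
#' @return Character vector of length 46.
#' @export
#' @examples
#' gp_names()
gp_names <- function() GP_NAMES

# Coerce a data frame (with GP columns) or matrix to a numeric matrix of
# peak abundances, preserving rows.  Errors name the first missing column.
as_gp_matrix <- function(x, cols = GP_NAMES) {
  if (is.data.frame(x)) {
    missing <- setdiff(cols, names(x))
    if (length(missing) > 0) {
      abort(paste0("missing glycan peak column: ", missing[1]))
    }
    x <- as.matrix(x[cols])
  } else {
    x <- as.matrix(x)
    if (is.null(colnames(x)) && ncol(x) == length(cols)) colnames(x) <- cols
  }
  storage.mode(x) <- "double"
  x
}

#' Close compositions to a constant total
#'
#' Rescales each row of non-negative peak abundances so that it sums to
#' `total` (100 by default, the percent-of-total-area convention).  Closure is
#' the defining operation of compositional data: only relative information is
#' retained.
#'
#' @param x A numeric vector (one composition), a matrix with one composition
#'   per row, or a data frame containing the `GP1..GP46` columns.
#' @param total Positive closure constant; default 100 (percent units).
#' @return Same shape as the input: a vector, matrix, or the data frame with
#'   its GP columns replaced by the closed values.
#' @export
#' @examples
#' close_composition(c(1, 1, 2), total = 100)
close_composition <- function(x, total = 100) {
  stopifnot(is.numeric(total), length(total) == 1, is.finite(total), total > 0)
  if (is.data.frame(x)) {
    m <- close_composition(as_gp_matrix(x), total)
    x[, colnames(m)] <- tibble::as_tibble(m)
    return(x)
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("compositions must be finite and non-negative")
  }
  s <- rowSums(m)
  if (any(s <= 0)) abort("degenerate composition: all parts zero")
  m <- m * (total / s)
  if (vec) {
    out <- drop(m)
    names(out) <- names(x)
    out
  } else {
    dimnames(m) <- dimnames(x)
    m
  }
}

#' Multiplicative replacement of zero peak areas
#'
#' Log-ratio transforms require strictly positive parts.  Each zero entry in
#' column `j` is imputed as half the smallest positive value observed in that
#' column; the non-zero entries of the affected row are shrunk
#' multiplicatively so the row still sums to the closure total.  Rows without
#' zeros are returned unchanged.
#'
#' @param x Matrix or data frame of closed compositions (rows sum to `total`).
#' @param total Closure constant, default 100.
#' @return Strictly positive object of the same shape, rows re-closed.
#' @export
replace_zeros <- function(x, total = 100) {
  if (is.data.frame(x)) {
    m <- replace_zeros(as_gp_matrix(x), total)
    x[, colnames(m)] <- tibble::as_tibble(m)
    return(x)
  }
  m <- as.matrix(x)
  if (!any(m == 0)) return(x)
  delta <- vapply(seq_len(ncol(m)), function(j) {
    pos <- m[m[, j] > 0, j]
    if (length(pos) == 0) {
      nm <- colnames(m)[j] %||% as.character(j)
      abort(paste0("peak ", nm, " is zero in every subject; cannot impute"))
    }
    0.5 * min(pos)
  }, numeric(1))
  for (i in which(rowSums(m == 0) > 0)) {
    z <- m[i, ] == 0
    repl <- sum(delta[z])
    m[i, !z] <- m[i, !z] * (total - repl) / total
    m[i, z] <- delta[z]
    m[i, ] <- m[i, ] * (total / sum(m[i, ]))
  }
  m
}

#' Orthonormal basis of the pivot ilr coordinates
#'
#' Returns the `D x (D-1)` matrix `V` whose columns are the clr-space
#' directions of the pivot (sequential binary partition) ilr coordinates:
#' coordinate `i` contrasts part `i` against the geometric mean of parts
#' `i+1..D`.  Satisfies `clr = V %*% ilr` and `t(V) %*% V = I`.
#'
#' @param D Number of parts (default 46).
#' @return A `D x (D-1)` matrix.
#' @export
ilr_basis <- function(D = N_PEAKS) {
  V <- matrix(0, D, D - 1)
  for (i in seq_len(D - 1)) {
    a <- sqrt((D - i) / (D - i + 1))
    V[i, i] <- a
    V[(i + 1):D, i] <- -a / (D - i)
  }
  V
}

#' Centered log-ratio transform
#'
#' `clr(x)_j = log(x_j / g(x))` with `g` the geometric mean of the row; the
#' result sums to zero across parts.
#'
#' @param x Strictly positive composition vector, matrix (rows), or data
#'   frame with GP columns.
#' @return Numeric vector or matrix of clr values (data frames are reduced to
#'   their GP columns).
#' @export
clr_transform <- function(x) {
  if (is.data.frame(x)) x <- as_gp_matrix(x)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort("clr requires strictly positive parts; run replace_zeros() first")
  }
  lm_ <- log(m)
  out <- lm_ - rowMeans(lm_)
  if (vec) drop(out) else out
}

#' Isometric log-ratio (pivot coordinate) transform
#'
#' Maps each D-part composition to `D - 1` unconstrained real coordinates
#' using pivot coordinates in the fixed `GP1..GP46` order:
#' `z_i = sqrt((D-i)/(D-i+1)) * log(x_i / g(x_{i+1..D}))`.  The map is an
#' isometry between the Aitchison geometry on the simplex and Euclidean
#' geometry, so distances, PCA and K-means in ilr space are the compositional
#' ones.
#'
#' @param x Strictly positive composition vector, matrix, or data frame with
#'   GP columns.
#' @return Vector of length `D - 1`, or a matrix with columns `z1..z45` (for
#'   a data frame input, a tibble of coordinates).
#' @export
#' @examples
#' ilr_transform(c(75, 25))  # sqrt(1/2) * log(3)
ilr_transform <- function(x) {
  df_in <- is.data.frame(x)
  cl <- clr_transform(x)
  vec <- is.null(dim(cl))
  m <- if (vec) matrix(cl, nrow = 1) else cl
  V <- ilr_basis(ncol(m))
  z <- m %*% V
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  if (df_in) return(tibble::as_tibble(z))
  if (vec) drop(z) else z
}

#' Inverse ilr transform
#'
#' Maps ilr coordinates back to compositions closed to `total`.  Exact
#' inverse of [ilr_transform()]: round trips agree to well below 1e-9.
#'
#' @param z Vector of `D - 1` coordinates or matrix with one coordinate
#'   vector per row.
#' @param total Closure constant, default 100.
#' @return Composition vector or matrix with `GP` column names when `D = 46`.
#' @export
ilr_inverse <- function(z, total = 100) {
  vec <- is.null(dim(z))
  m <- if (vec) matrix(as.numeric(z), nrow = 1) else as.matrix(z)
  if (any(!is.finite(m))) abort("ilr coordinates must be finite")
  D <- ncol(m) + 1L
  cl <- m %*% t(ilr_basis(D))
  e <- exp(cl)
  comp <- e * (total / rowSums(e))
  colnames(comp) <- if (D == N_PEAKS) GP_NAMES else paste0("part", seq_len(D))
  if (vec) drop(comp) else comp
}

#' Aitchison distance between compositions
#'
#' Euclidean distance between clr (equivalently ilr) images; the natural
#' metric on the simplex.
#'
#' @param x,y Strictly positive composition vectors of equal length.
#' @return Non-negative scalar.
#' @export
aitchison_distance <- function(x, y) {
  sqrt(sum((clr_transform(x) - clr_transform(y))^2))
}

#' Spearman correlation of ilr coordinates
#'
#' Rank correlations between the 45 pivot coordinates across subjects.
#' Coordinates with no variation yield `NA` entries with a warning.
#'
#' @param x Data frame with GP columns, a composition matrix (rows are
#'   subjects), or an ilr coordinate matrix (45 columns).
#' @return A symmetric 45 x 45 correlation matrix with unit diagonal.
#' @export
spearman_ilr <- function(x) {
  if (is.data.frame(x)) x <- as_gp_matrix(x)
  m <- as.matrix(x)
  if (ncol(m) == N_PEAKS) m <- ilr_transform(replace_zeros(close_composition(m)))
  if (nrow(m) < 3) abort("need at least 3 subjects for correlation")
  constant <- apply(m, 2, function(v) diff(range(v)) == 0)
  r <- suppressWarnings(stats::cor(m, method = "spearman"))
  diag(r) <- 1
  if (any(constant)) {
    warn(paste0("constant ilr coordinate(s): ",
                paste(colnames(m)[constant], collapse = ", "),
                "; correlations reported as NA"))
    r[constant, ] <- NA_real_
    r[, constant] <- NA_real_
    diag(r) <- 1
  }
  r
}
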