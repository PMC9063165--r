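#' Centred log-ratio (clr) transform
#'
#' Maps each sample's strictly positive composition to log abundances centred
#' by the sample's mean log abundance, so that the transformed parts sum to
#' zero and the result is invariant to per-sample scaling (sequencing depth).
#'
#' @param x An `abund_tbl` with strictly positive values (see
#'   [replace_zeros()]), or a positive numeric matrix/vector.
#' @return A tibble with `sample_id` plus one clr coordinate per feature (for
#'   tables), or a matrix/vector mirroring the input shape.
#' @export
clr_transform <- function(x) {
  if (inherits(x, "abund_tbl")) {
    m <- clr_matrix(abund_matrix(x))
    return(bind_cols(tibble(sample_id = x$sample_id), as_tibble(m)))
  }
  if (is.matrix(x)) return(clr_matrix(x))
  drop(clr_matrix(matrix(x, nrow = 1)))
}

clr_matrix <- function(m) {
  if (any(m <= 0)) abort("clr needs strictly positive parts; run replace_zeros() first")
  lm <- log(m)
  lm - rowMeans(lm)
}

#' Isometric log-ratio (ilr) transform with a pivot basis
#'
#' Maps a D-part composition to D-1 orthonormal log-contrast coordinates. The
#' default basis is the pivot (sequential binary) partition over features in
#' the order given by `order_features` (feature id by default): coordinate j
#' contrasts part j against the geometric mean of parts j+1..D,
#' `sqrt((D-j)/(D-j+1)) * log(x_j / g(x_{j+1..D}))`. The transform is an
#' isometry of the clr geometry: Euclidean norms (and hence PCA variance
#' downstream) do not depend on the particular basis.
#'
#' @param x An `abund_tbl` with strictly positive values, or a positive
#'   matrix/vector.
#' @param order_features How to order parts before the pivot partition:
#'   `"id"` (lexicographic feature id, the default) or `"given"` (column
#'   order as supplied).
#' @return A tibble with `sample_id` plus coordinates `ilr_1..ilr_{D-1}`, or a
#'   matrix/vector for matrix/vector input.
#' @export
ilr_transform <- function(x, order_features = c("id", "given")) {
  order_features <- match.arg(order_features)
  if (inherits(x, "abund_tbl")) {
    m <- abund_matrix(x)
    if (order_features == "id") m <- m[, order(colnames(m)), drop = FALSE]
    out <- ilr_matrix(m)
    return(bind_cols(tibble(sample_id = x$sample_id), as_tibble(out)))
  }
  if (is.matrix(x)) {
    if (order_features == "id" && !is.null(colnames(x))) {
      x <- x[, order(colnames(x)), drop = FALSE]
    }
    return(ilr_matrix(x))
  }
  drop(ilr_matrix(matrix(x, nrow = 1)))
}

ilr_matrix <- function(m) {
  if (any(m <= 0)) abort("ilr needs strictly positive parts; run replace_zeros() first")
  d <- ncol(m)
  if (d < 2L) abort("ilr needs at least 2 parts")
  lm <- log(m)
  out <- matrix(0, nrow(m), d - 1L)
  for (j in seq_len(d - 1L)) {
    tail_mean <- rowMeans(lm[, (j + 1L):d, drop = FALSE])
    out[, j] <- sqrt((d - j) / (d - j + 1)) * (lm[, j] - tail_mean)
  }
  colnames(out) <- paste0("ilr_", seq_len(d - 1L))
  rownames(out) <- rownames(m)
  out
}

#' Define a balance between two disjoint feature groups
#'
#' A balance is a normalised log contrast between the geometric means of a
#' numerator and a denominator feature set of sizes r and s:
#' `sqrt(r*s/(r+s)) * log(g(numerator)/g(denominator))`. Balances are the
#' compositional predictors used by the block classifiers.
#'
#' @param numerator,denominator Disjoint, non-empty character vectors of
#'   feature ids.
#' @return An object of class `balance`.
#' @export
balance <- function(numerator, denominator) {
  numerator <- unique(as.character(numerator))
  denominator <- unique(as.character(denominator))
  if (!length(numerator) || !length(denominator)) {
    abort("numerator and denominator must each contain at least one feature")
  }
  if (length(intersect(numerator, denominator))) {
    abort("numerator and denominator must be disjoint")
  }
  structure(list(numerator = numerator, denominator = denominator),
            class = "balance")
}

#' @export
print.balance <- function(x, ...) {
  cat(sprintf("<balance> %d vs %d features, coefficient %.5f\n",
              length(x$numerator), length(x$denominator),
              balance_coefficient(x)))
  invisible(x)
}

balance_coefficient <- function(b) {
  r <- length(b$numerator); s <- length(b$denominator)
  sqrt(r * s / (r + s))
}

#' Evaluate a balance on an abundance table
#'
#' @param x An `abund_tbl` with strictly positive values.
#' @param b A [balance()].
#' @return A tibble with columns `sample_id` and `value`.
#' @export
balance_value <- function(x, b) {
  m <- abund_matrix(x)
  miss <- setdiff(c(b$numerator, b$denominator), colnames(m))
  if (length(miss)) {
    abort(paste0("balance features missing from table: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  tibble(sample_id = x$sample_id,
         value = balance_value_matrix(m, b))
}

balance_value_matrix <- function(m, b) {
  if (any(m <= 0)) abort("balance needs strictly positive parts")
  lm <- log(m)
  num <- rowMeans(lm[, b$numerator, drop = FALSE])
  den <- rowMeans(lm[, b$denominator, drop = FALSE])
  unname(balance_coefficient(b) * (num - den))
}
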