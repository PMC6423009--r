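# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` (any case) so that mixed dialects such as `"chr3"`
#' and `"3"` compare equal across cohorts.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector without the `"chr"` prefix.
#' @examples
#' normalize_chromosome(c("chr3", "3", "chrX"))
#' @export
normalize_chromosome <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

#' Cosine similarity between two vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @return Cosine similarity in `[-1, 1]`; 0 when either vector is all zeros.
#' @examples
#' cosine_similarity(c(1, 0, 1), c(1, 1, 0))
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

# Column-wise cosine similarity matrix between columns of A (m x p) and B (m x q).
cosine_matrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  An <- sqrt(colSums(A^2)); Bn <- sqrt(colSums(B^2))
  An[An == 0] <- 1; Bn[Bn == 0] <- 1
  crossprod(A, B) / outer(An, Bn)
}

# Stop with a named-column format error if required columns are missing.
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s: missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Validate a numeric scalar lies in a range.
check_range <- function(x, lo, hi, name, lo_open = FALSE, hi_open = FALSE) {
  bad <- !is.numeric(x) | is.na(x) |
    (if (lo_open) x <= lo else x < lo) |
    (if (hi_open) x >= hi else x > hi)
  if (any(bad)) {
    abort(sprintf("`%s` must be in %s%g, %g%s", name,
                  if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"))
  }
  invisible(x)
}

# Adjusted Rand index between two labelings (used by tests and reported by
# subtype recovery checks).
#' Adjusted Rand index
#'
#' Agreement between two partitions of the same items, corrected for chance.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return Numeric scalar; 1 for identical partitions, ~0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
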