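#' Graded-lexicographic exponent table for bivariate monomials
#'
#' Enumerates the exponent pairs (a, b) of all monomials `T^a * P^b` with
#' total degree `a + b <= degree`, in graded lexicographic order: the
#' intercept first, then within each total degree g the terms
#' `T^g, T^(g-1) P, ..., P^g`.
#'
#' @param degree Maximum total degree, an integer in `[1, 6]`.
#' @return A tibble with columns `a`, `b`, `total_degree`, one row per term;
#'   `choose(degree + 2, 2)` rows in all.
#' @export
polynomial_exponents <- function(degree) {
  if (!is.numeric(degree) || length(degree) != 1 || degree < 1 || degree != round(degree)) {
    abort("degree must be a positive integer", class = "solubag_validation_error")
  }
  rows <- list(tibble::tibble(a = 0L, b = 0L))
  for (g in seq_len(degree)) {
    rows[[g + 1L]] <- tibble::tibble(a = as.integer(g:0), b = as.integer(0:g))
  }
  out <- dplyr::bind_rows(rows)
  out$total_degree <- out$a + out$b
  out
}

#' Evaluate polynomial feature expansion
#'
#' Expands (T, P) feature rows into the full interaction monomial basis of
#' [polynomial_exponents()].  The first column is the intercept term 1.
#'
#' @param X A numeric matrix (or 2-column data frame) of feature rows.
#' @param degree Maximum total degree.
#' @return A numeric matrix with `choose(degree + 2, 2)` columns, named
#'   `T^a.P^b`, with attribute `"total_degree"` giving each term's degree.
#' @examples
#' polynomial_terms(matrix(c(2, 3), 1), degree = 2)  # 1, 2, 3, 4, 6, 9
#' @export
polynomial_terms <- function(X, degree) {
  X <- as.matrix(X)
  if (ncol(X) != 2) {
    abort("X must have exactly two columns (T, P)", class = "solubag_validation_error")
  }
  ex <- polynomial_exponents(degree)
  out <- matrix(0, nrow(X), nrow(ex))
  for (j in seq_len(nrow(ex))) {
    out[, j] <- X[, 1]^ex$a[j] * X[, 2]^ex$b[j]
  }
  colnames(out) <- paste0("T^", ex$a, ".P^", ex$b)
  attr(out, "total_degree") <- ex$total_degree
  out
}

# Standardization state: per-feature mean and standard deviation.
make_scaler <- function(X) {
  X <- as.matrix(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1  # constant feature: leave centred at zero
  list(center = colMeans(X), scale = s)
}

apply_scaler <- function(X, scaler) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}
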