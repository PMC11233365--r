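#' Exact rational matrices
#'
#' A minimal dense matrix of exact rationals, stored as parallel numerator and
#' denominator matrices. Used internally for index matrices, split-pair
#' incidence matrices and their right inverses, where ranks, inverses and
#' products must be exact. Elimination is plain fraction-based Gauss-Jordan
#' with the first non-zero pivot; with exact arithmetic no pivoting strategy
#' is needed for correctness.
#'
#' @param x a `pdindex_rq` vector of length `nrow * ncol`, in column-major
#'   order, or an integer-valued numeric matrix.
#' @param nrow,ncol dimensions (taken from `x` when it is a matrix).
#' @param dimnames optional list of row and column names.
#' @return An object of class `rq_matrix`.
#' @export
rq_matrix <- function(x, nrow = NULL, ncol = NULL, dimnames = NULL) {
  if (is.matrix(x)) {
    nrow <- base::nrow(x)
    ncol <- base::ncol(x)
    if (is.null(dimnames)) dimnames <- base::dimnames(x)
    x <- as_rq(as.vector(x))
  }
  stopifnot(inherits(x, "pdindex_rq"), length(x) == nrow * ncol)
  n <- matrix(rq_num(x), nrow, ncol)
  d <- matrix(rq_den(x), nrow, ncol)
  if (!is.null(dimnames)) {
    base::dimnames(n) <- dimnames
    base::dimnames(d) <- dimnames
  }
  structure(list(n = n, d = d), class = "rq_matrix")
}

#' @export
dim.rq_matrix <- function(x) dim(x$n)

#' @export
dimnames.rq_matrix <- function(x) dimnames(x$n)

rqm_nrow <- function(x) nrow(x$n)
rqm_ncol <- function(x) ncol(x$n)

# whole matrix (or a row/column) as an rq vector, column-major
rqm_values <- function(x) rq_canonical(as.vector(x$n), as.vector(x$d))

rqm_row <- function(x, i) rq_canonical(unname(x$n[i, ]), unname(x$d[i, ]))
rqm_col <- function(x, j) rq_canonical(unname(x$n[, j]), unname(x$d[, j]))

rqm_entry <- function(x, i, j) rq(x$n[i, j], x$d[i, j])

rqm_set <- function(x, i, j, value) {
  value <- as_rq(value)
  x$n[i, j] <- rq_num(value)
  x$d[i, j] <- rq_den(value)
  x
}

#' @export
`[.rq_matrix` <- function(x, i, j, ...) {
  structure(list(n = x$n[i, j, drop = FALSE], d = x$d[i, j, drop = FALSE]),
            class = "rq_matrix")
}

rqm_identity <- function(n, labels = NULL) {
  dn <- if (is.null(labels)) NULL else list(labels, labels)
  rq_matrix(diag(n), dimnames = dn)
}

rqm_zero <- function(nrow, ncol, dimnames = NULL) {
  rq_matrix(matrix(0, nrow, ncol), dimnames = dimnames)
}

#' @export
print.rq_matrix <- function(x, ...) {
  m <- matrix(format(rqm_values(x)), rqm_nrow(x), rqm_ncol(x),
              dimnames = dimnames(x))
  cat("<rq_matrix: ", rqm_nrow(x), " x ", rqm_ncol(x), ">\n", sep = "")
  print(m, quote = FALSE)
  invisible(x)
}

#' Exact matrix product
#' @param a,b `rq_matrix` objects with compatible dimensions.
#' @return An `rq_matrix`.
#' @export
rqm_mult <- function(a, b) {
  stopifnot(rqm_ncol(a) == rqm_nrow(b))
  out <- rqm_zero(rqm_nrow(a), rqm_ncol(b),
                  dimnames = list(rownames(a$n), colnames(b$n)))
  for (i in seq_len(rqm_nrow(a))) {
    ra <- rqm_row(a, i)
    for (j in seq_len(rqm_ncol(b))) {
      out <- rqm_set(out, i, j, rq_dot(ra, rqm_col(b, j)))
    }
  }
  out
}

rqm_equal <- function(a, b) {
  identical(dim(a$n), dim(b$n)) && all(a$n == b$n) && all(a$d == b$d)
}

rqm_row_sums <- function(x) {
  out <- vctrs::vec_init(new_rq(), rqm_nrow(x))
  for (i in seq_len(rqm_nrow(x))) out[i] <- rq_sum(rqm_row(x, i))
  out
}

# in-place row operation row_i <- row_i - f * row_k on the (n, d) pair
rqm_axpy_row <- function(x, i, k, f) {
  ri <- rq_add(rqm_row(x, i), rq_neg(rq_mul(f, rqm_row(x, k))))
  x$n[i, ] <- rq_num(ri)
  x$d[i, ] <- rq_den(ri)
  x
}

#' Exact rank of a rational matrix
#' @param x an `rq_matrix`.
#' @return Integer rank over the rationals.
#' @export
rqm_rank <- function(x) {
  m <- rqm_nrow(x)
  n <- rqm_ncol(x)
  rank <- 0L
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    piv <- which(x$n[row:m, col] != 0)
    if (length(piv) == 0) next
    piv <- piv[1] + row - 1L
    if (piv != row) {
      x$n[c(row, piv), ] <- x$n[c(piv, row), ]
      x$d[c(row, piv), ] <- x$d[c(piv, row), ]
    }
    pval <- rqm_entry(x, row, col)
    for (i in seq_len(m)) {
      if (i != row && x$n[i, col] != 0) {
        f <- rq_mul(rqm_entry(x, i, col), rq_inv(pval))
        x <- rqm_axpy_row(x, i, row, f)
      }
    }
    rank <- rank + 1L
    row <- row + 1L
  }
  rank
}

#' Exact inverse of a square rational matrix
#' @param x a square `rq_matrix` of full rank.
#' @return The inverse as an `rq_matrix`.
#' @export
rqm_inverse <- function(x) {
  n <- rqm_nrow(x)
  stopifnot(n == rqm_ncol(x))
  inv <- rqm_identity(n)
  dimnames(inv$n) <- list(colnames(x$n), rownames(x$n))
  dimnames(inv$d) <- dimnames(inv$n)
  for (col in seq_len(n)) {
    piv <- which(x$n[col:n, col] != 0)
    if (length(piv) == 0) stop("matrix is singular", call. = FALSE)
    piv <- piv[1] + col - 1L
    if (piv != col) {
      x$n[c(col, piv), ] <- x$n[c(piv, col), ]
      x$d[c(col, piv), ] <- x$d[c(piv, col), ]
      inv$n[c(col, piv), ] <- inv$n[c(piv, col), ]
      inv$d[c(col, piv), ] <- inv$d[c(piv, col), ]
    }
    pinv <- rq_inv(rqm_entry(x, col, col))
    rx <- rq_mul(rqm_row(x, col), pinv)
    ri <- rq_mul(rqm_row(inv, col), pinv)
    x$n[col, ] <- rq_num(rx); x$d[col, ] <- rq_den(rx)
    inv$n[col, ] <- rq_num(ri); inv$d[col, ] <- rq_den(ri)
    for (i in seq_len(n)) {
      if (i != col && x$n[i, col] != 0) {
        f <- rqm_entry(x, i, col)
        x <- rqm_axpy_row(x, i, col, f)
        inv <- rqm_axpy_row(inv, i, col, f)
      }
    }
  }
  inv
}
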