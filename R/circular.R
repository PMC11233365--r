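# ---- circular split systems and Pauplin-type indices ------------------------

pair_keys <- function(tx) {
  if (length(tx) < 2) return(character(0))
  apply(utils::combn(tx, 2), 2, function(p) cluster_key(p))
}

#' Full circular split system of an ordering
#'
#' For an ordering x_0, ..., x_{n-1} of the taxa, the full circular system
#' consists of all splits whose first part is an interval x_i..x_j with
#' 0 <= i <= j < n-1 (the intervals avoiding the last element); there are
#' exactly n(n-1)/2 of them, the maximum any circular system can have.
#'
#' @param ordering character vector of at least 3 taxa.
#' @return An unweighted `pdindex_splits` with the ordering attached as
#'   attribute `"ordering"`.
#' @export
full_circular_system <- function(ordering) {
  ordering <- as.character(ordering)
  n <- length(ordering)
  if (n < 3) stop("a full circular system needs at least 3 taxa", call. = FALSE)
  sides <- list()
  for (i in seq_len(n - 1)) {
    for (j in i:(n - 1)) {
      sides[[length(sides) + 1]] <- ordering[i:j]
    }
  }
  out <- split_system(sides, taxa = ordering)
  attr(out, "ordering") <- ordering
  out
}

#' Split-pair incidence matrix
#'
#' The 0/1 matrix M(S) with one row per split and one column per 2-element
#' subset of X, recording which splits separate which pairs. A weighting
#' lambda induces the pairwise distances d_lambda = lambda * M. For circular
#' split systems the rows are linearly independent, so distinct weightings
#' give distinct distances; for a full circular system M is square and
#' invertible.
#'
#' @param ss a split system on at least 2 taxa.
#' @return An [rq_matrix] with rows labelled by split and columns by pair
#'   (`"x,y"` in lexicographic order).
#' @export
pair_incidence <- function(ss) {
  tx <- taxa(ss)
  pk <- pair_keys(tx)
  pairs <- utils::combn(tx, 2)
  m <- matrix(0, nrow(ss), length(pk), dimnames = list(ss$label, pk))
  for (i in seq_len(nrow(ss))) {
    ina <- pairs[1, ] %in% ss$side_a[[i]]
    inb <- pairs[2, ] %in% ss$side_a[[i]]
    m[i, xor(ina, inb)] <- 1
  }
  rq_matrix(m)
}

#' Pairwise distances induced by a split weighting
#'
#' d({x,y}) is the total weight of the splits separating x from y
#' (d_lambda = lambda * M for the incidence matrix M). Non-negative
#' weightings give a metric-like distance table exportable with
#' [write_phylip_distances()].
#'
#' @param sw a weighted split system.
#' @return A tibble of class `pdindex_distances` with columns `x`, `y` and
#'   exact rational `distance`, one row per unordered pair.
#' @export
split_distances <- function(sw) {
  tx <- taxa(sw)
  m <- pair_incidence(sw)
  pairs <- utils::combn(tx, 2)
  d <- vctrs::vec_init(new_rq(), ncol(pairs))
  for (j in seq_len(ncol(pairs))) d[j] <- rq_dot(sw$weight, rqm_col(m, j))
  out <- tibble::new_tibble(
    list(x = pairs[1, ], y = pairs[2, ], distance = d),
    nrow = ncol(pairs), class = "pdindex_distances"
  )
  attr(out, "taxa") <- tx
  out
}

# interval positions (0-based a..b, avoiding the last ordering element)
split_interval <- function(side_a, side_b, ordering) {
  n <- length(ordering)
  side <- if (ordering[n] %in% side_a) side_b else side_a
  pos <- sort(match(side, ordering))
  if (pos[length(pos)] - pos[1] + 1 != length(pos)) {
    stop("split is not circular with respect to the ordering", call. = FALSE)
  }
  c(a = pos[1] - 1L, b = pos[length(pos)] - 1L)
}

new_right_inverse <- function(r, splits, ordering = NULL) {
  structure(list(r = r, splits = splits, ordering = ordering),
            class = "pdindex_rinv")
}

#' @export
print.pdindex_rinv <- function(x, ...) {
  cat("# Right inverse of a split-pair incidence matrix (",
      rqm_nrow(x$r), " pairs x ", length(x$splits), " splits)\n", sep = "")
  print(x$r)
  invisible(x)
}

validate_right_inverse <- function(ss, r) {
  m <- pair_incidence(ss)
  prod <- rqm_mult(m, r)
  if (!rqm_equal(prod, rqm_identity(nrow(ss), ss$label))) {
    stop("M(S) * R is not the identity: not a right inverse", call. = FALSE)
  }
  invisible(TRUE)
}

#' Wrap and validate a user-supplied right inverse
#'
#' Any matrix R with M(S) * R = I defines a complete linear index through
#' [psi_r()]; this constructor checks that identity exactly before accepting
#' R.
#'
#' @param ss a circular split system.
#' @param entries an [rq_matrix] (or character matrix of fractions) with one
#'   row per taxon pair (lexicographic order, as in [pair_incidence()]) and
#'   one column per split in system order.
#' @return An object of class `pdindex_rinv`.
#' @export
right_inverse <- function(ss, entries) {
  tx <- taxa(ss)
  pk <- pair_keys(tx)
  if (is.character(entries)) {
    entries <- rq_matrix(as_rq(as.vector(entries)), length(pk), nrow(ss),
                         dimnames = list(pk, ss$label))
  }
  stopifnot(inherits(entries, "rq_matrix"),
            rqm_nrow(entries) == length(pk), rqm_ncol(entries) == nrow(ss))
  dimnames(entries$n) <- list(pk, ss$label)
  dimnames(entries$d) <- dimnames(entries$n)
  validate_right_inverse(ss, entries)
  new_right_inverse(entries, ss$label)
}

#' Closed-form right inverse for a full circular system
#'
#' For the full circular system of an ordering, M(S) is square and its unique
#' inverse has an explicit sparse form: the column of the split with interval
#' x_a..x_b has entries +1/2 at the pairs \{x_a, x_(b+1 mod n)\} and
#' \{x_(a-1 mod n), x_b\}, and -1/2 at \{x_a, x_b\} and
#' \{x_(a-1 mod n), x_(b+1 mod n)\} (degenerate pairs skipped, coincident
#' pairs accumulated). The construction is validated by asserting
#' M * R = I exactly, so an index-convention error cannot pass silently.
#'
#' @param ordering character vector of at least 3 taxa.
#' @return An object of class `pdindex_rinv` for [full_circular_system()] of
#'   the ordering.
#' @export
full_right_inverse <- function(ordering) {
  ss <- full_circular_system(ordering)
  ordering <- attr(ss, "ordering")
  n <- length(ordering)
  pk <- pair_keys(taxa(ss))
  r <- rqm_zero(length(pk), nrow(ss), dimnames = list(pk, ss$label))
  add_entry <- function(r, y, z, col, value) {
    if (y == z) return(r)  # degenerate pair
    i <- match(cluster_key(c(y, z)), pk)
    r <- rqm_set(r, i, col, rqm_entry(r, i, col) + value)
    r
  }
  half <- rq(1, 2)
  for (j in seq_len(nrow(ss))) {
    ab <- split_interval(ss$side_a[[j]], ss$side_b[[j]], ordering)
    xa <- ordering[ab["a"] + 1L]
    xb <- ordering[ab["b"] + 1L]
    xa1 <- ordering[(ab["a"] - 1L) %% n + 1L]  # x_(a-1 mod n)
    xb1 <- ordering[(ab["b"] + 1L) %% n + 1L]  # x_(b+1 mod n)
    r <- add_entry(r, xa, xb1, j, half)
    r <- add_entry(r, xa1, xb, j, half)
    r <- add_entry(r, xa, xb, j, -half)
    r <- add_entry(r, xa1, xb1, j, -half)
  }
  validate_right_inverse(ss, r)
  new_right_inverse(r, ss$label, ordering)
}

#' Pauplin-type index from a right inverse
#'
#' Given a circular split system with weighting lambda and a right inverse R
#' of its incidence matrix, evaluates
#' Psi_R(x) = 1/2 * sum over y != x, sum over splits S of
#' d_lambda({x,y}) * r_({x,y},S). Every such index is complete and linear,
#' whatever right inverse is chosen; on a full circular system R is unique
#' and the index has the closed-form matrix of [pauplin_gamma()].
#'
#' @param sw a weighted circular split system.
#' @param rinv a `pdindex_rinv` for this system (defaults to the closed-form
#'   inverse when the system is full circular with a known ordering).
#' @return A `pdindex_index` tibble.
#' @export
psi_r <- function(sw, rinv = NULL) {
  rinv <- rinv %||% full_right_inverse(attr(sw, "ordering") %||%
    stop("supply a right inverse or a system with an ordering attribute", call. = FALSE))
  if (!identical(rinv$splits, sw$label)) {
    stop("right inverse does not match the split system", call. = FALSE)
  }
  tx <- taxa(sw)
  d <- split_distances(sw)
  dkey <- vapply(seq_len(nrow(d)), function(i) cluster_key(c(d$x[i], d$y[i])), "")
  vals <- vctrs::vec_init(new_rq(), length(tx))
  for (j in seq_along(tx)) {
    acc <- rq(0)
    for (y in setdiff(tx, tx[j])) {
      i <- match(cluster_key(c(tx[j], y)), rownames(rinv$r$n))
      acc <- acc + d$distance[match(cluster_key(c(tx[j], y)), dkey)] *
        rq_sum(rqm_row(rinv$r, i))
    }
    vals[j] <- acc * rq(1, 2)
  }
  new_div_index(tx, vals, "psi_R")
}

#' Index matrix of a Pauplin-type index
#'
#' The |S| x |X| matrix Gamma with entries
#' gamma_(S,x) = 1/2 * sum over y != x, sum over splits S' of
#' m_(S,{x,y}) * r_({x,y},S'); applying it to a weighting reproduces
#' [psi_r()]. All row sums equal 1 exactly (completeness), but entries may
#' be negative for some right inverses.
#'
#' @param ss a circular split system.
#' @param rinv a `pdindex_rinv` for `ss`.
#' @return A `pdindex_gamma` (split-based).
#' @export
psi_r_matrix <- function(ss, rinv) {
  if (!identical(rinv$splits, ss$label)) {
    stop("right inverse does not match the split system", call. = FALSE)
  }
  tx <- taxa(ss)
  m <- pair_incidence(ss)
  rho <- rqm_row_sums(rinv$r)  # per pair, summed over splits
  pk <- rownames(rinv$r$n)
  gamma <- rqm_zero(nrow(ss), length(tx), dimnames = list(ss$label, tx))
  for (i in seq_len(nrow(ss))) {
    for (j in seq_along(tx)) {
      acc <- rq(0)
      for (y in setdiff(tx, tx[j])) {
        p <- match(cluster_key(c(tx[j], y)), pk)
        if (m$n[i, p] != 0) acc <- acc + rho[p]
      }
      gamma <- rqm_set(gamma, i, j, acc * rq(1, 2))
    }
  }
  new_gamma(gamma, ss, "psi_R", "split")
}

cyclic_part_info <- function(part, ordering) {
  n <- length(ordering)
  pos <- sort(match(part, ordering)) - 1L  # 0-based
  k <- length(pos)
  if (k == n) stop("a split part cannot be all of X", call. = FALSE)
  # find the cyclic start: position whose predecessor (mod n) is absent
  present <- logical(n)
  present[pos + 1L] <- TRUE
  starts <- pos[!present[(pos - 1L) %% n + 1L]]
  if (length(starts) != 1) {
    stop("split is not circular with respect to the ordering", call. = FALSE)
  }
  list(start = starts, end = (starts + k - 1L) %% n, size = k)
}

#' Closed-form matrix entry of the full-system Pauplin index
#'
#' For the full circular system of an ordering, the unique right inverse
#' gives an index matrix with a three-valued pattern: an entry is 1/2 when
#' the part of the split containing the taxon is a singleton, 1/4 when the
#' taxon is a cyclic endpoint of a larger part, and 0 when it is interior.
#'
#' @param ordering character vector of at least 3 taxa.
#' @param split one side of a split of the full circular system (member
#'   vector or comma-separated string).
#' @param x a taxon label.
#' @return A length-one exact rational.
#' @export
pauplin_gamma_entry <- function(ordering, split, x) {
  ordering <- as.character(ordering)
  side <- check_subset(split, ordering)
  part <- if (x %in% side) side else setdiff(ordering, side)
  if (!x %in% ordering) stop("unknown taxon: ", x, call. = FALSE)
  info <- cyclic_part_info(part, ordering)
  pos <- match(x, ordering) - 1L
  if (info$size == 1) return(rq(1, 2))
  if (pos == info$start || pos == info$end) return(rq(1, 4))
  rq(0)
}

#' Closed-form index matrix of the full circular system
#'
#' Assembles the full-system Pauplin index matrix entry by entry from the
#' three-valued closed form; it coincides with [psi_r_matrix()] applied to
#' the closed-form right inverse, and with explicit exact inversion of the
#' incidence matrix.
#'
#' @param ordering character vector of at least 3 taxa.
#' @return A `pdindex_gamma` (split-based) on [full_circular_system()].
#' @export
pauplin_gamma <- function(ordering) {
  ss <- full_circular_system(ordering)
  tx <- taxa(ss)
  gamma <- rqm_zero(nrow(ss), length(tx), dimnames = list(ss$label, tx))
  for (i in seq_len(nrow(ss))) {
    for (j in seq_along(tx)) {
      gamma <- rqm_set(gamma, i, j,
                       pauplin_gamma_entry(attr(ss, "ordering"), ss$side_a[[i]], tx[j]))
    }
  }
  new_gamma(gamma, ss, "psi_R (closed form)", "split")
}

#' Pauplin-type indices for non-full circular systems
#'
#' A circular system that is not full inherits two natural indices from the
#' full system of its ordering: `"gamma_rows"` restricts the closed-form
#' full-system index matrix to the rows of the present splits, while
#' `"inverse_columns"` restricts the full-system right inverse to the
#' columns of the present splits (the restriction is itself a right inverse
#' of M(S), which is verified) and takes its index matrix. Both indices are
#' complete; they generally differ.
#'
#' @param ss a split system circular with respect to `ordering`.
#' @param ordering character vector of the taxa in circular order.
#' @param method `"gamma_rows"` or `"inverse_columns"`.
#' @return A `pdindex_gamma` (split-based) on `ss`.
#' @export
restricted_psi <- function(ss, ordering, method = c("gamma_rows", "inverse_columns")) {
  method <- match.arg(method)
  ordering <- check_ordering(ordering, taxa(ss))
  if (!is_circular_with(ss, ordering)) {
    stop("system is not circular with respect to the ordering", call. = FALSE)
  }
  full <- full_circular_system(ordering)
  idx <- match(ss$label, full$label)
  if (anyNA(idx)) stop("split missing from the full circular system", call. = FALSE)
  if (method == "gamma_rows") {
    g <- pauplin_gamma(ordering)
    out <- new_gamma(g$gamma[idx, ], ss, "psi_1 (row restriction)", "split")
  } else {
    rfull <- full_right_inverse(ordering)
    r <- rfull$r[, idx]
    validate_right_inverse(ss, r)
    out <- psi_r_matrix(ss, new_right_inverse(r, ss$label, ordering))
    out$index <- "psi_2 (column restriction)"
  }
  out
}
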