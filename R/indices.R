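# ---- index vectors ----------------------------------------------------------

new_div_index <- function(taxa, values, index) {
  out <- tibble::new_tibble(
    list(taxon = taxa, value = values),
    nrow = length(taxa), class = "pdindex_index"
  )
  attr(out, "taxa") <- taxa
  attr(out, "index") <- index
  out
}

#' @export
print.pdindex_index <- function(x, ...) {
  cat("# Diversity index <", attr(x, "index"), "> on ", nrow(x), " taxa",
      " (total ", format(rq_sum(x$value)), ")\n", sep = "")
  NextMethod()
}

#' Extract index values for given taxa
#' @param index a diversity index vector (class `pdindex_index`).
#' @param taxon taxon label(s); defaults to all.
#' @return A `pdindex_rq` vector in the order of `taxon`.
#' @export
index_value <- function(index, taxon = NULL) {
  taxon <- taxon %||% index$taxon
  i <- match(taxon, index$taxon)
  if (anyNA(i)) stop("unknown taxon: ", paste(taxon[is.na(i)], collapse = ", "), call. = FALSE)
  index$value[i]
}

cluster_membership <- function(cs) {
  tx <- taxa(cs)
  m <- matrix(FALSE, nrow(cs), length(tx), dimnames = list(cs$label, tx))
  for (i in seq_len(nrow(cs))) m[i, cs$cluster[[i]]] <- TRUE
  m
}

# ---- fair proportion --------------------------------------------------------

#' Fair proportion index on a weighted cluster system
#'
#' Each cluster shares its weight equally among its members:
#' FP(omega)(x) = sum over clusters C containing x of omega(C)/|C|. On the
#' hierarchy of a rooted tree this is the classical fair proportion
#' (evolutionary distinctiveness) index; the same formula applies verbatim to
#' arbitrary cluster systems. The result is complete: the values sum exactly
#' to the total cluster weight.
#'
#' @param cw a weighted cluster system (see [cluster_system()]).
#' @return A `pdindex_index` tibble with one exact rational value per taxon.
#' @examples
#' cw <- example_cluster_weighting()
#' fair_proportion(cw)
#' @export
fair_proportion <- function(cw) {
  tx <- taxa(cw)
  vals <- vctrs::vec_init(new_rq(), length(tx))
  for (j in seq_along(tx)) {
    inC <- vapply(cw$cluster, function(m) tx[j] %in% m, TRUE)
    vals[j] <- if (any(inC)) rq_sum(cw$weight[inC] / rq(cw$size[inC])) else rq(0)
  }
  new_div_index(tx, vals, "fair_proportion")
}

# ---- equal splits -----------------------------------------------------------

#' Equal splits coefficients of a cluster system
#'
#' The recursive coefficients m_x(C) that define the equal splits index: a
#' cluster C divides its weight into |ch(C)| + |cl(C)| equal shares, one per
#' child cluster and one per member not covered by any child; a taxon's share
#' of a child's portion is determined recursively. If C has no children,
#' m_x(C) = 1/|C| for its members. Every row sums to 1 exactly. The recursion
#' is evaluated over clusters in increasing size order (children are strictly
#' smaller), with the formula applied verbatim also on non-hierarchies, where
#' overlapping children each contribute their share.
#'
#' @param cs a cluster system (weights are ignored).
#' @return An [rq_matrix] with one row per cluster (in system order) and one
#'   column per taxon.
#' @export
equal_splits_coefficients <- function(cs) {
  tx <- taxa(cs)
  k <- nrow(cs)
  m <- rqm_zero(k, length(tx), dimnames = list(cs$label, tx))
  # rows are already sorted by increasing size, a valid evaluation order
  for (i in seq_len(k)) {
    ch <- children(cs, cs$cluster[[i]])
    cl <- setdiff(cs$cluster[[i]], unlist(ch))
    denom <- rq(length(ch) + length(cl))
    for (x in cl) m <- rqm_set(m, i, match(x, tx), rq(1) / denom)
    covered <- setdiff(cs$cluster[[i]], cl)
    if (length(ch) > 0 && length(covered) > 0) {
      ch_rows <- match(vapply(ch, cluster_key, ""), cs$label)
      for (x in covered) {
        j <- match(x, tx)
        contrib <- rq_sum(rq_canonical(m$n[ch_rows, j], m$d[ch_rows, j]))
        m <- rqm_set(m, i, j, contrib / denom)
      }
    }
  }
  m
}

#' Equal splits index on a weighted cluster system
#'
#' ES(omega)(x) = sum over clusters C of m_x(C) * omega(C), with the
#' coefficients of [equal_splits_coefficients()]. On a rooted tree this is
#' the classical equal splits index of conservation prioritization; it is a
#' complete linear index on every cluster system.
#'
#' @inheritParams fair_proportion
#' @return A `pdindex_index` tibble.
#' @export
equal_splits <- function(cw) {
  m <- equal_splits_coefficients(cw)
  tx <- taxa(cw)
  vals <- vctrs::vec_init(new_rq(), length(tx))
  for (j in seq_along(tx)) vals[j] <- rq_dot(cw$weight, rqm_col(m, j))
  new_div_index(tx, vals, "equal_splits")
}

# ---- index matrices ---------------------------------------------------------

new_gamma <- function(gamma, system, index, kind) {
  structure(
    list(gamma = gamma, rows = rownames(gamma$n), taxa = colnames(gamma$n),
         system = system, index = index, kind = kind),
    class = "pdindex_gamma"
  )
}

#' @export
print.pdindex_gamma <- function(x, ...) {
  cat("# Index matrix <", x$index, "> (", x$kind, "-based), ",
      length(x$rows), " x ", length(x$taxa), "\n", sep = "")
  print(x$gamma)
  invisible(x)
}

#' The matrix of a linear cluster-based index
#'
#' Every linear index corresponds to a |C| x |X| matrix Gamma with
#' (Phi(omega))(x) = sum_C omega(C) * gamma_(C,x). For the fair proportion
#' index the row of cluster C has |C| entries equal to 1/|C| and zeros
#' elsewhere; for the equal splits index the entries are the recursive
#' coefficients m_x(C).
#'
#' @param cs a cluster system.
#' @param index `"fair_proportion"` or `"equal_splits"`.
#' @return A `pdindex_gamma` object; use [apply_index_matrix()] to evaluate
#'   it on a weighting and [check_properties()] to inspect its axioms.
#' @export
index_matrix <- function(cs, index = c("fair_proportion", "equal_splits")) {
  index <- match.arg(index)
  if (index == "fair_proportion") {
    memb <- cluster_membership(cs)
    g <- rqm_zero(nrow(cs), length(taxa(cs)), dimnames = dimnames(memb))
    g$n[memb] <- 1
    g$d <- matrix(rep(cs$size, length(taxa(cs))), nrow(cs), length(taxa(cs)),
                  dimnames = dimnames(memb))
    gamma <- rq_matrix(rqm_values(g), nrow(cs), length(taxa(cs)),
                       dimnames = dimnames(memb))
  } else {
    gamma <- equal_splits_coefficients(cs)
  }
  new_gamma(gamma, cs, index, "cluster")
}

#' Construct an index matrix from explicit entries
#'
#' Wraps a user-supplied matrix of exact rationals as a linear cluster-based
#' index, for use with the property checkers.
#'
#' @param cs the cluster system indexing the rows (in system row order).
#' @param entries an [rq_matrix], a `pdindex_rq` vector (column-major), or a
#'   character matrix of fractions, with `nrow(cs)` rows and one column per
#'   taxon.
#' @return A `pdindex_gamma` object with index name `"custom"`.
#' @export
custom_index_matrix <- function(cs, entries) {
  tx <- taxa(cs)
  if (is.character(entries)) entries <- as_rq(as.vector(entries))
  if (inherits(entries, "pdindex_rq")) {
    entries <- rq_matrix(entries, nrow(cs), length(tx),
                         dimnames = list(cs$label, tx))
  }
  stopifnot(inherits(entries, "rq_matrix"),
            rqm_nrow(entries) == nrow(cs), rqm_ncol(entries) == length(tx))
  dimnames(entries$n) <- list(cs$label, tx)
  dimnames(entries$d) <- list(cs$label, tx)
  new_gamma(entries, cs, "custom", "cluster")
}

#' Evaluate a linear index through its matrix
#'
#' Computes omega * Gamma, the index vector of a weighting under the linear
#' index represented by `gamma`. This is an independent evaluation route used
#' to cross-check the direct summation formulas.
#'
#' @param gamma a `pdindex_gamma`.
#' @param weighting a weighted system whose labels match the matrix rows; by
#'   default the system stored in `gamma` (with its weights).
#' @return A `pdindex_index` tibble.
#' @export
apply_index_matrix <- function(gamma, weighting = NULL) {
  weighting <- weighting %||% gamma$system
  if (!identical(weighting$label, gamma$rows)) {
    stop("weighting rows do not match the index matrix rows", call. = FALSE)
  }
  vals <- vctrs::vec_init(new_rq(), length(gamma$taxa))
  for (j in seq_along(gamma$taxa)) {
    vals[j] <- rq_dot(weighting$weight, rqm_col(gamma$gamma, j))
  }
  new_div_index(gamma$taxa, vals, paste0(gamma$index, " (matrix)"))
}

# ---- restriction ------------------------------------------------------------

#' Remove a cluster or split from a weighted system
#'
#' Deletes one cluster (or split) while keeping the taxa and all other
#' weights; this is the restriction underlying downward continuity. Note that
#' structural quantities such as children and equal-splits coefficients are
#' recomputed on the restricted system.
#'
#' @param system a weighted cluster or split system with at least two rows.
#' @param element a cluster (member vector or string) or a split label
#'   identifying the row to remove.
#' @return The restricted system.
#' @export
restrict <- function(system, element) {
  i <- if (inherits(system, "pdindex_clusters")) {
    cluster_index_of(system, element)
  } else {
    j <- match(split_key(parse_members(sub("\\|.*$", "", element)), taxa(system)),
               system$label)
    if (is.na(j)) stop("split not in the system", call. = FALSE)
    j
  }
  if (nrow(system) < 2) stop("cannot remove the last element of a system", call. = FALSE)
  out <- system[-i, ]
  attr(out, "taxa") <- taxa(system)
  class(out) <- class(system)
  out
}

# ---- property checkers ------------------------------------------------------

#' Check the structural axioms of an index matrix
#'
#' Inspects a linear cluster-based index through its matrix:
#' \describe{
#'   \item{complete}{every row sums to exactly 1, equivalent to the index
#'     values always summing to the total weight;}
#'   \item{nonnegative}{no negative entries;}
#'   \item{neutrality}{for every cluster without children, all its members
#'     receive equal entries;}
#'   \item{descendant_diversity}{complete, non-negative, and zero entries for
#'     taxa outside the cluster.}
#' }
#' These are the axioms that, over all cluster systems jointly, single out
#' the fair proportion index. A single matrix can satisfy all of them without
#' being the fair proportion matrix (see [example_nonfp_matrix()]).
#'
#' @param gamma a `pdindex_gamma` (cluster-based).
#' @param cs the cluster system; defaults to the one stored in `gamma`.
#' @return A list of class `pdindex_properties` with logical flags and a
#'   `notes` character vector of violation witnesses.
#' @export
check_properties <- function(gamma, cs = NULL) {
  cs <- cs %||% gamma$system
  if (!identical(cs$label, gamma$rows)) {
    stop("system does not match the matrix rows", call. = FALSE)
  }
  tx <- gamma$taxa
  notes <- character()
  rs <- rqm_row_sums(gamma$gamma)
  bad <- which(!(rq_num(rs) == 1 & rq_den(rs) == 1))
  complete <- length(bad) == 0
  if (!complete) {
    notes <- c(notes, paste0("row {", gamma$rows[bad], "} sums to ", format(rs[bad])))
  }
  nonnegative <- all(gamma$gamma$n >= 0)
  if (!nonnegative) notes <- c(notes, "matrix has negative entries")

  if (gamma$kind == "split") {
    # neutrality and descendant diversity are cluster-side axioms
    return(structure(
      list(complete = complete, nonnegative = nonnegative,
           neutrality = NA, descendant_diversity = NA, notes = notes),
      class = "pdindex_properties"
    ))
  }

  neutrality <- TRUE
  for (i in seq_len(nrow(cs))) {
    if (length(children(cs, cs$cluster[[i]])) == 0) {
      cols <- match(cs$cluster[[i]], tx)
      vals <- rq_canonical(gamma$gamma$n[i, cols], gamma$gamma$d[i, cols])
      if (length(vals) > 1 &&
          !(all(rq_num(vals) == rq_num(vals[1])) && all(rq_den(vals) == rq_den(vals[1])))) {
        neutrality <- FALSE
        notes <- c(notes, paste0("childless cluster {", cs$label[i],
                                 "} has unequal member entries"))
      }
    }
  }

  memb <- cluster_membership(cs)
  outside_zero <- all(gamma$gamma$n[!memb] == 0)
  if (!outside_zero) notes <- c(notes, "non-zero entry for a taxon outside its cluster")
  descendant_diversity <- complete && nonnegative && outside_zero

  structure(
    list(complete = complete, nonnegative = nonnegative,
         neutrality = neutrality, descendant_diversity = descendant_diversity,
         notes = notes),
    class = "pdindex_properties"
  )
}

#' @export
print.pdindex_properties <- function(x, ...) {
  flags <- vapply(x[c("complete", "nonnegative", "neutrality", "descendant_diversity")],
                  isTRUE, TRUE)
  cat("# Index property report\n")
  for (nm in names(flags)) cat(sprintf("  %-21s %s\n", nm, if (flags[nm]) "yes" else "no"))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Check downward continuity of a pair of linear indices
#'
#' A linear index on a system C is downward continuous with respect to an
#' index on C minus one cluster if letting that cluster's weight tend to zero
#' reproduces the smaller index. For linear indices this holds exactly when
#' deleting the corresponding row from the larger matrix yields the smaller
#' matrix, which is what is tested (structurally, not by numeric limits).
#'
#' @param gamma index matrix on the full system.
#' @param gamma_star index matrix on the system without `cluster`.
#' @param cluster the removed cluster (member vector or string).
#' @return `TRUE` or `FALSE`.
#' @export
check_downward_continuity <- function(gamma, gamma_star, cluster) {
  key <- cluster_key(parse_members(cluster))
  i <- match(key, gamma$rows)
  if (is.na(i)) stop("cluster {", key, "} is not a row of the full matrix", call. = FALSE)
  if (!identical(gamma$rows[-i], gamma_star$rows)) {
    stop("matrices are not on matching systems", call. = FALSE)
  }
  rqm_equal(gamma$gamma[-i, ], gamma_star$gamma)
}
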