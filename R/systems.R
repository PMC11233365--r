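#' @importFrom rlang %||%
#' @importFrom vctrs vec_ptype2 vec_cast vec_arith vec_math vec_ptype_abbr
#' @importFrom vctrs vec_proxy_compare vec_arith.numeric
NULL

# ---- canonical labels -------------------------------------------------------

check_taxa <- function(taxa) {
  taxa <- as.character(taxa)
  if (length(taxa) < 1) stop("a taxon set must contain at least one taxon", call. = FALSE)
  if (anyDuplicated(taxa)) stop("duplicate taxon labels", call. = FALSE)
  if (any(taxa == "" | is.na(taxa))) stop("empty taxon label", call. = FALSE)
  if (any(grepl("[,|]", taxa))) stop("taxon labels must not contain ',' or '|'", call. = FALSE)
  sort(taxa)
}

cluster_key <- function(members) paste(sort(members), collapse = ",")

split_parts <- function(side, taxa) {
  other <- setdiff(taxa, side)
  if (length(side) == 0 || length(other) == 0) {
    stop("both parts of a split must be non-empty", call. = FALSE)
  }
  # canonical form: the part containing the lexicographically smallest taxon first
  if (min(taxa) %in% side) list(a = sort(side), b = sort(other))
  else list(a = sort(other), b = sort(side))
}

split_key <- function(side, taxa) {
  p <- split_parts(side, taxa)
  paste0(paste(p$a, collapse = ","), "|", paste(p$b, collapse = ","))
}

parse_members <- function(x) {
  if (is.character(x) && length(x) == 1 && grepl(",", x)) {
    strsplit(x, ",")[[1]]
  } else {
    as.character(x)
  }
}

#' Taxa of a system, tree or index
#'
#' @param x a cluster system, split system, weighted tree or index vector.
#' @return Character vector of taxon labels in canonical (sorted) order.
#' @export
taxa <- function(x) attr(x, "taxa")

# ---- cluster systems --------------------------------------------------------

#' Weighted cluster systems
#'
#' A cluster system is a non-empty collection of distinct non-empty subsets
#' (clusters) of a taxon set X, each optionally carrying a real weight. Rooted
#' phylogenetic trees correspond to the special case of a hierarchy, with one
#' cluster per edge (the leaves below it) weighted by the branch length, but
#' arbitrary, even overlapping, collections are allowed. A cluster with weight
#' zero is still a structural member of the system; removing a cluster is the
#' explicit [restrict()] operation.
#'
#' @param clusters a list of character vectors (cluster members), a character
#'   vector of comma-separated member strings, or a data frame with a
#'   `cluster` column (and optionally a `weight` column).
#' @param weights optional weights, one per cluster: rationals created by
#'   [rq()]/[as_rq()], integer-valued numerics, or strings like `"3/4"`.
#'   Defaults to zero.
#' @param taxa optional taxon set; defaults to the union of the clusters.
#'
#' @return A tibble of class `pdindex_clusters` with columns `cluster`
#'   (list of member vectors), `label`, `size` and `weight` (exact rational),
#'   ordered by increasing cluster size then label. The taxon set is stored
#'   as an attribute and recovered with [taxa()].
#' @examples
#' cs <- cluster_system(list(c("a", "b"), "a", "b"), weights = c(4, 3, 2))
#' taxa(cs)
#' @export
cluster_system <- function(clusters, weights = NULL, taxa = NULL) {
  if (is.data.frame(clusters)) {
    if (is.null(weights) && "weight" %in% names(clusters)) weights <- clusters$weight
    clusters <- clusters$cluster
  }
  if (is.character(clusters)) clusters <- lapply(clusters, parse_members)
  if (length(clusters) == 0) stop("a cluster system must contain at least one cluster", call. = FALSE)
  clusters <- lapply(clusters, function(m) sort(unique(as.character(m))))
  if (any(lengths(clusters) == 0)) stop("clusters must be non-empty", call. = FALSE)
  taxa <- check_taxa(taxa %||% unique(unlist(clusters)))
  unknown <- setdiff(unlist(clusters), taxa)
  if (length(unknown) > 0) {
    stop("cluster members not in the taxon set: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  weights <- if (is.null(weights)) rq_zero(length(clusters)) else as_rq(weights)
  weights <- vctrs::vec_recycle(weights, length(clusters))

  labels <- vapply(clusters, cluster_key, "")
  if (anyDuplicated(labels)) {
    keep <- !duplicated(labels)
    merged <- vctrs::vec_init(new_rq(), sum(keep))
    for (i in seq_along(labels[keep])) {
      merged[i] <- rq_sum(weights[labels == labels[keep][i]])
    }
    if (any(table(labels) > 1) && any(!rq_is_zero(weights[duplicated(labels)]))) {
      warning("duplicate clusters merged; weights summed", call. = FALSE)
    }
    clusters <- clusters[keep]
    labels <- labels[keep]
    weights <- merged
  }
  ord <- order(lengths(clusters), labels)
  out <- tibble::new_tibble(
    list(cluster = clusters[ord], label = labels[ord],
         size = lengths(clusters)[ord], weight = weights[ord]),
    nrow = length(ord), class = "pdindex_clusters"
  )
  attr(out, "taxa") <- taxa
  out
}

#' @export
print.pdindex_clusters <- function(x, ...) {
  cat("# A cluster system on {", paste(taxa(x), collapse = ", "), "}: ",
      nrow(x), " clusters\n", sep = "")
  NextMethod()
}

#' Replace the weights of a system
#'
#' @param system a cluster or split system.
#' @param weights new weights (rational, integer-valued numeric or strings),
#'   either unnamed in row order or named by cluster/split label.
#' @return The system with its `weight` column replaced.
#' @export
set_weights <- function(system, weights) {
  w <- as_rq(unname(weights))
  if (!is.null(names(weights))) {
    idx <- match(system$label, names(weights))
    if (anyNA(idx)) stop("weights missing for: ",
                         paste(system$label[is.na(idx)], collapse = "; "), call. = FALSE)
    w <- w[idx]
  }
  system$weight <- vctrs::vec_recycle(w, nrow(system))
  system
}

#' Total weight of a system
#' @param system a cluster or split system.
#' @return Exact rational sum of all weights.
#' @export
total_weight <- function(system) rq_sum(system$weight)

cluster_index_of <- function(cs, members) {
  key <- cluster_key(parse_members(members))
  i <- match(key, cs$label)
  if (is.na(i)) stop("cluster {", key, "} is not in the system", call. = FALSE)
  i
}

#' Test whether a cluster system is a hierarchy
#'
#' A hierarchy has every pair of clusters nested or disjoint; these are
#' exactly the cluster systems representable by a rooted phylogenetic tree.
#'
#' @param cs a cluster system.
#' @return `TRUE` or `FALSE`.
#' @export
is_hierarchy <- function(cs) {
  k <- nrow(cs)
  if (k < 2) return(TRUE)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      common <- length(intersect(cs$cluster[[i]], cs$cluster[[j]]))
      if (common > 0 && common < min(cs$size[i], cs$size[j])) return(FALSE)
    }
  }
  TRUE
}

#' Child clusters within a system
#'
#' The children ch(C) of a cluster C are the maximal proper subsets of C
#' present in the system: clusters C' with C' strictly inside C and no other
#' cluster strictly between them. Children are determined by the system's
#' structure alone, so zero-weight clusters participate.
#'
#' @param cs a cluster system.
#' @param cluster a member vector or comma-separated string identifying a
#'   cluster of `cs`.
#' @return A list of member vectors (possibly empty).
#' @export
children <- function(cs, cluster) {
  i <- cluster_index_of(cs, cluster)
  target <- cs$cluster[[i]]
  proper <- which(vapply(cs$cluster, function(m) {
    length(m) < length(target) && all(m %in% target)
  }, TRUE))
  keep <- vapply(proper, function(p) {
    !any(vapply(proper, function(q) {
      q != p && all(cs$cluster[[p]] %in% cs$cluster[[q]]) &&
        length(cs$cluster[[p]]) < length(cs$cluster[[q]])
    }, TRUE))
  }, TRUE)
  cs$cluster[proper[keep]]
}

#' Taxa of a cluster covered by none of its children
#'
#' cl(C): the members of C that lie in no child of C. When C has no children
#' this is all of C.
#'
#' @inheritParams children
#' @return Character vector of taxon labels.
#' @export
cluster_free_taxa <- function(cs, cluster) {
  i <- cluster_index_of(cs, cluster)
  setdiff(cs$cluster[[i]], unlist(children(cs, cluster)))
}

#' Number of taxa covered by the children of a cluster
#'
#' desc(C) = |union of ch(C)|. Children may overlap, so in general this is at
#' most the sum of the child sizes.
#'
#' @inheritParams children
#' @return Integer count.
#' @export
descendant_count <- function(cs, cluster) {
  length(unique(unlist(children(cs, cluster))))
}

# ---- split systems ----------------------------------------------------------

#' Weighted split systems
#'
#' A split is a bipartition A|B of the taxon set X; a split system is a
#' non-empty set of distinct splits, each optionally weighted. Unrooted
#' phylogenetic trees correspond to compatible split systems, with one split
#' per edge weighted by the branch length. Splits are stored canonically with
#' the part containing the lexicographically smallest taxon first.
#'
#' @param splits one side of each split: a list of character vectors, a
#'   character vector of comma-separated member strings (a full `"a,b|c,d"`
#'   label is also accepted), or a data frame with a `split` column (and
#'   optionally `weight`).
#' @param weights optional weights, as in [cluster_system()].
#' @param taxa the taxon set (required unless full `A|B` labels are given and
#'   cover it).
#'
#' @return A tibble of class `pdindex_splits` with columns `side_a`, `side_b`
#'   (lists of member vectors), `label`, `size_a`, `size_b` and `weight`,
#'   ordered by label. The taxon set is stored as an attribute.
#' @examples
#' ss <- split_system(list(c("a", "b")), weights = 7, taxa = letters[1:5])
#' ss$label
#' @export
split_system <- function(splits, weights = NULL, taxa = NULL) {
  if (is.data.frame(splits)) {
    if (is.null(weights) && "weight" %in% names(splits)) weights <- splits$weight
    splits <- splits$split
  }
  if (is.character(splits)) {
    splits <- lapply(splits, function(s) parse_members(sub("\\|.*$", "", s)))
  }
  if (length(splits) == 0) stop("a split system must contain at least one split", call. = FALSE)
  splits <- lapply(splits, function(m) sort(unique(as.character(m))))
  taxa <- check_taxa(taxa %||% unique(unlist(splits)))
  unknown <- setdiff(unlist(splits), taxa)
  if (length(unknown) > 0) {
    stop("split members not in the taxon set: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  weights <- if (is.null(weights)) rq_zero(length(splits)) else as_rq(weights)
  weights <- vctrs::vec_recycle(weights, length(splits))

  parts <- lapply(splits, split_parts, taxa = taxa)
  labels <- vapply(seq_along(parts), function(i) {
    paste0(paste(parts[[i]]$a, collapse = ","), "|", paste(parts[[i]]$b, collapse = ","))
  }, "")
  if (anyDuplicated(labels)) {
    keep <- !duplicated(labels)
    merged <- vctrs::vec_init(new_rq(), sum(keep))
    for (i in seq_along(labels[keep])) {
      merged[i] <- rq_sum(weights[labels == labels[keep][i]])
    }
    if (any(!rq_is_zero(weights[duplicated(labels)]))) {
      warning("duplicate splits merged; weights summed", call. = FALSE)
    }
    parts <- parts[keep]
    labels <- labels[keep]
    weights <- merged
  }
  ord <- order(labels)
  out <- tibble::new_tibble(
    list(side_a = lapply(parts[ord], `[[`, "a"),
         side_b = lapply(parts[ord], `[[`, "b"),
         label = labels[ord],
         size_a = vapply(parts[ord], function(p) length(p$a), 1L),
         size_b = vapply(parts[ord], function(p) length(p$b), 1L),
         weight = weights[ord]),
    nrow = length(ord), class = "pdindex_splits"
  )
  attr(out, "taxa") <- taxa
  out
}

#' @export
print.pdindex_splits <- function(x, ...) {
  cat("# A split system on {", paste(taxa(x), collapse = ", "), "}: ",
      nrow(x), " splits\n", sep = "")
  NextMethod()
}

splits_compatible_pair <- function(a1, b1, a2, b2) {
  length(intersect(a1, a2)) == 0 || length(intersect(a1, b2)) == 0 ||
    length(intersect(b1, a2)) == 0 || length(intersect(b1, b2)) == 0
}

#' Test pairwise compatibility of a split system
#'
#' Two splits A|B and C|D are compatible if at least one of the intersections
#' A&C, A&D, B&C, B&D is empty; a pairwise compatible split system is exactly
#' one displayable by an unrooted phylogenetic tree.
#'
#' @param ss a split system.
#' @return `TRUE` or `FALSE`.
#' @export
is_compatible <- function(ss) {
  k <- nrow(ss)
  if (k < 2) return(TRUE)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (!splits_compatible_pair(ss$side_a[[i]], ss$side_b[[i]],
                                  ss$side_a[[j]], ss$side_b[[j]])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

check_ordering <- function(ordering, taxa) {
  ordering <- as.character(ordering)
  if (!setequal(ordering, taxa) || length(ordering) != length(taxa)) {
    stop("ordering must be a permutation of the taxon set", call. = FALSE)
  }
  ordering
}

is_circular_with <- function(ss, ordering) {
  n <- length(ordering)
  for (i in seq_len(nrow(ss))) {
    # the part avoiding the last element of the ordering must be an interval
    side <- if (ordering[n] %in% ss$side_a[[i]]) ss$side_b[[i]] else ss$side_a[[i]]
    pos <- sort(match(side, ordering))
    if (pos[length(pos)] - pos[1] + 1 != length(pos)) return(FALSE)
  }
  TRUE
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

#' Test circularity of a split system
#'
#' A split system is circular for an ordering x_0, ..., x_{n-1} of X if every
#' split has a part that is a contiguous interval of the ordering avoiding
#' x_{n-1}; equivalently, the system is contained in the full circular system
#' of that ordering. With `ordering = NULL` all cyclic orderings are searched
#' exhaustively (up to rotation and reflection), which is limited to at most
#' 8 taxa.
#'
#' @param ss a split system.
#' @param ordering optional character vector permuting `taxa(ss)`.
#' @return `TRUE` or `FALSE`. When an ordering is found by search it is
#'   attached as attribute `"ordering"` of the returned value.
#' @export
is_circular <- function(ss, ordering = NULL) {
  tx <- taxa(ss)
  if (!is.null(ordering)) {
    return(is_circular_with(ss, check_ordering(ordering, tx)))
  }
  n <- length(tx)
  if (n > 8) {
    stop("exhaustive circularity search is limited to 8 taxa; supply an ordering",
         call. = FALSE)
  }
  if (n <= 3) {
    return(structure(TRUE, ordering = tx))
  }
  rest <- tx[-1]
  for (perm in permutations_of(rest)) {
    # quotient reflections: keep orderings with second element before last
    if (match(perm[1], tx) > match(perm[length(perm)], tx)) next
    ord <- c(tx[1], perm)
    if (is_circular_with(ss, ord)) return(structure(TRUE, ordering = ord))
  }
  FALSE
}

#' The cluster system induced by a split system
#'
#' Collects both parts of every split into one deduplicated cluster system
#' C(S); this is the affine shadow of the projective object S, and the system
#' on which lifted indices are evaluated.
#'
#' @param ss a split system.
#' @return An unweighted `pdindex_clusters` on the same taxa.
#' @export
clusters_of_splits <- function(ss) {
  cluster_system(c(ss$side_a, ss$side_b), taxa = taxa(ss))
}

#' Maximal compatible subsystems of a split system
#'
#' All inclusion-maximal subsets of the splits that are pairwise compatible,
#' found as the maximal cliques of the compatibility graph. Weights are
#' carried over. Guarded to systems of at most 20 splits.
#'
#' @param ss a split system.
#' @return A list of `pdindex_splits`, each on the full taxon set.
#' @export
maximal_compatible_subsystems <- function(ss) {
  k <- nrow(ss)
  if (k > 20) stop("exhaustive search limited to 20 splits", call. = FALSE)
  if (k == 1) return(list(ss))
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      adj[i, j] <- adj[j, i] <- splits_compatible_pair(
        ss$side_a[[i]], ss$side_b[[i]], ss$side_a[[j]], ss$side_b[[j]])
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(g)
  out <- lapply(cliques, function(v) {
    idx <- sort(as.integer(v))
    split_system(ss$side_a[idx], weights = ss$weight[idx], taxa = taxa(ss))
  })
  # deterministic order: by decreasing size, then by concatenated labels
  keys <- vapply(out, function(s) paste(s$label, collapse = ";"), "")
  out[order(-vapply(out, nrow, 1L), keys)]
}
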