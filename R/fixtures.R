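# ---- worked example on five taxa -------------------------------------------

#' Worked example: a five-taxon weighted tree and its systems
#'
#' A small rooted tree on X = \{a, b, c, d, e\} with integer branch lengths
#' totalling 25, used throughout the documentation and tests.
#' `example_tree_newick()` returns its Newick string;
#' `example_cluster_weighting()` the 8-cluster hierarchy induced by its
#' edges; `example_split_weighting()` the 7-split system of the unrooted
#' tree (the two root edges merge into one split of weight 7). The fair
#' proportion index of the cluster weighting is (5, 4, 7, 3, 6).
#'
#' @return A Newick string, a weighted cluster system, or a weighted split
#'   system, respectively.
#' @examples
#' fair_proportion(example_cluster_weighting())
#' @export
example_tree_newick <- function() {
  "((a:3,b:2):4,(c:6,(d:1,e:4):2):3);"
}

#' @rdname example_tree_newick
#' @export
example_cluster_weighting <- function() {
  cluster_system(
    list("a", "b", "c", "d", "e", c("a", "b"), c("d", "e"), c("c", "d", "e")),
    weights = c(3, 2, 6, 1, 4, 4, 2, 3)
  )
}

#' @rdname example_tree_newick
#' @export
example_split_weighting <- function() {
  split_system(
    list("a", "b", "c", "d", "e", c("a", "b"), c("d", "e")),
    weights = c(3, 2, 6, 1, 4, 7, 2),
    taxa = c("a", "b", "c", "d", "e")
  )
}

#' Worked example: an overlapping (non-hierarchical) cluster system
#'
#' The system \{\{a,b,c\}, \{c,d\}, X\} on five taxa, in which the children of
#' X overlap in c and e belongs to no child; the equal splits coefficient of
#' e in X is exactly 1/3.
#'
#' @return An unweighted cluster system.
#' @export
example_overlapping_clusters <- function() {
  cluster_system(
    list(c("a", "b", "c"), c("c", "d"), c("a", "b", "c", "d", "e")),
    taxa = c("a", "b", "c", "d", "e")
  )
}

#' A complete, neutral, descendant-diversity matrix that is not fair proportion
#'
#' On the chain system \{\{a,b\}, \{a,b,c,d\}, \{a,b,c,d,e\}\} this explicit
#' matrix passes the completeness, neutrality and descendant-diversity
#' checks and is downward continuous with respect to its own row deletions,
#' yet differs from the fair proportion matrix — showing that those checks
#' on a single system do not pin down fair proportion; the characterization
#' needs all cluster systems at once.
#'
#' @return A list with the cluster system `system` and the `pdindex_gamma`
#'   matrix `gamma`.
#' @export
example_nonfp_matrix <- function() {
  cs <- cluster_system(
    list(c("a", "b"), c("a", "b", "c", "d"), c("a", "b", "c", "d", "e")),
    taxa = c("a", "b", "c", "d", "e")
  )
  entries <- matrix(
    c("1/2", "1/2", "0", "0", "0",
      "1/4", "1/4", "1/4", "1/4", "0",
      "2/5", "2/5", "1/15", "1/15", "1/15"),
    nrow = 3, byrow = TRUE
  )
  list(system = cs, gamma = custom_index_matrix(cs, as_rq(as.vector(entries))))
}

# ---- seeded random generators -----------------------------------------------

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

default_taxa <- function(n) {
  if (n <= 26) letters[seq_len(n)] else paste0("t", sprintf("%02d", seq_len(n)))
}

#' Seeded random systems and weightings
#'
#' Deterministic generators for test and simulation inputs.
#' `random_hierarchy()` builds a hierarchy by random binary agglomeration
#' (all merge clusters plus the singletons). `random_cluster_system()`
#' samples k distinct non-empty subsets uniformly; `random_split_system()`
#' samples k distinct splits; `random_circular_split_system()` samples k
#' splits from the full circular system of a random ordering (returned as
#' attribute `"ordering"`). `random_weighting()` attaches random rational
#' weights p/q with numerators 1..max_num (negated with probability
#' `negative`) and denominators from `denominators`.
#'
#' @param n_taxa number of taxa (labels `a`, `b`, ... ).
#' @param k number of clusters/splits requested (capped at the number
#'   available).
#' @param seed integer seed; the global RNG state is restored afterwards.
#' @return A system, or (for `random_weighting`) the input system with new
#'   weights.
#' @export
random_hierarchy <- function(n_taxa, seed) {
  with_seed(seed, {
    groups <- as.list(default_taxa(n_taxa))
    clusters <- groups
    while (length(groups) > 1) {
      i <- sample.int(length(groups), 2)
      merged <- sort(unlist(groups[i]))
      groups <- c(groups[-i], list(merged))
      clusters <- c(clusters, list(merged))
    }
    cluster_system(clusters, taxa = default_taxa(n_taxa))
  })
}

#' @rdname random_hierarchy
#' @export
random_cluster_system <- function(n_taxa, k, seed) {
  with_seed(seed, {
    tx <- default_taxa(n_taxa)
    k <- min(k, 2^n_taxa - 1)
    masks <- sample.int(2^n_taxa - 1L, k)
    clusters <- lapply(masks, function(m) {
      tx[bitwAnd(m, bitwShiftL(1L, seq_len(n_taxa) - 1L)) != 0L]
    })
    cluster_system(clusters, taxa = tx)
  })
}

#' @rdname random_hierarchy
#' @export
random_split_system <- function(n_taxa, k, seed) {
  stopifnot(n_taxa >= 2)
  with_seed(seed, {
    tx <- default_taxa(n_taxa)
    nsplit <- 2^(n_taxa - 1) - 1
    k <- min(k, nsplit)
    seen <- character(0)
    sides <- list()
    while (length(sides) < k) {
      m <- sample.int(2^n_taxa - 2L, 1)
      side <- tx[bitwAnd(m, bitwShiftL(1L, seq_len(n_taxa) - 1L)) != 0L]
      key <- split_key(side, tx)
      if (!key %in% seen) {
        seen <- c(seen, key)
        sides[[length(sides) + 1]] <- side
      }
    }
    split_system(sides, taxa = tx)
  })
}

#' @rdname random_hierarchy
#' @export
random_circular_split_system <- function(n_taxa, k, seed) {
  stopifnot(n_taxa >= 3)
  with_seed(seed, {
    tx <- default_taxa(n_taxa)
    ordering <- sample(tx)
    full <- full_circular_system(ordering)
    k <- min(k, nrow(full))
    idx <- sort(sample.int(nrow(full), k))
    out <- split_system(full$side_a[idx], taxa = tx)
    attr(out, "ordering") <- ordering
    out
  })
}

#' @rdname random_hierarchy
#' @param system a cluster or split system to weight.
#' @param max_num largest numerator magnitude.
#' @param denominators candidate denominators.
#' @param negative probability of a negative weight.
#' @export
random_weighting <- function(system, seed, max_num = 9,
                             denominators = c(1, 2, 3, 4, 6), negative = 0) {
  with_seed(seed, {
    k <- nrow(system)
    num <- sample.int(max_num, k, replace = TRUE)
    sgn <- ifelse(stats::runif(k) < negative, -1, 1)
    den <- sample(denominators, k, replace = TRUE)
    ord <- attr(system, "ordering")
    out <- set_weights(system, rq(sgn * num, den))
    attr(out, "ordering") <- ord
    out
  })
}
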