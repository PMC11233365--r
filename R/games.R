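# ---- phylogenetic diversity set functions -----------------------------------

check_subset <- function(members, tx) {
  members <- parse_members(members)
  unknown <- setdiff(members, tx)
  if (length(unknown) > 0) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  unique(members)
}

#' Phylogenetic diversity of a taxon subset (cluster form)
#'
#' PD(M) is the total weight of the clusters having non-empty intersection
#' with M. For the hierarchy of a rooted tree this is Faith's phylogenetic
#' diversity: the weight of all edges on a path from the root to some member
#' of M.
#'
#' @param cw a weighted cluster system.
#' @param members a subset of the taxa (character vector or comma-separated
#'   string); may be empty.
#' @return An exact rational.
#' @examples
#' pd_clusters(example_cluster_weighting(), c("a", "b", "d"))
#' @export
pd_clusters <- function(cw, members) {
  members <- check_subset(members, taxa(cw))
  if (length(members) == 0) return(rq(0))
  hit <- vapply(cw$cluster, function(m) length(intersect(m, members)) > 0, TRUE)
  rq_sum(cw$weight[hit])
}

#' Phylogenetic diversity of a taxon subset (split form)
#'
#' The total weight of the splits separating at least one pair of members of
#' M, i.e. splits with both parts meeting M. Subsets of size at most one have
#' diversity zero.
#'
#' @param sw a weighted split system.
#' @inheritParams pd_clusters
#' @return An exact rational.
#' @export
pd_splits <- function(sw, members) {
  members <- check_subset(members, taxa(sw))
  if (length(members) <= 1) return(rq(0))
  hit <- vapply(seq_len(nrow(sw)), function(i) {
    length(intersect(sw$side_a[[i]], members)) > 0 &&
      length(intersect(sw$side_b[[i]], members)) > 0
  }, TRUE)
  rq_sum(sw$weight[hit])
}

# ---- games ------------------------------------------------------------------

#' Cooperative games on the taxon set
#'
#' A game assigns an exact rational gain to every coalition (subset of taxa);
#' the games arising here all assign 0 to the empty coalition, which is
#' enforced at construction. `unit_game()` is the indicator game of a cluster
#' C (gain 1 whenever the coalition meets C); the phylogenetic diversity
#' games of [pd_game()] and [pd_game_splits()] are weighted sums of unit
#' games.
#'
#' @param taxa character vector of players.
#' @param f a function taking a character vector (a coalition) and returning
#'   a single exact rational (or an integer-valued numeric).
#' @return An object of class `pd_game`.
#' @export
game <- function(taxa, f) {
  taxa <- check_taxa(taxa)
  g <- function(members) as_rq(f(members))
  if (!isTRUE(g(character(0)) == rq(0))) {
    stop("games must assign 0 to the empty coalition", call. = FALSE)
  }
  structure(list(taxa = taxa, f = g), class = "pd_game")
}

#' @export
print.pd_game <- function(x, ...) {
  cat("# A game on {", paste(x$taxa, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Evaluate a game on a coalition
#' @param g a `pd_game`.
#' @param members a subset of the players.
#' @return An exact rational.
#' @export
game_value <- function(g, members) {
  g$f(check_subset(members, g$taxa))
}

#' @rdname game
#' @param cluster the cluster whose indicator game is taken.
#' @export
unit_game <- function(taxa, cluster) {
  taxa <- check_taxa(taxa)
  cluster <- check_subset(cluster, taxa)
  if (length(cluster) == 0) stop("the cluster of a unit game must be non-empty", call. = FALSE)
  game(taxa, function(members) {
    if (length(intersect(cluster, members)) > 0) 1 else 0
  })
}

#' @rdname game
#' @param cw a weighted cluster system.
#' @export
pd_game <- function(cw) {
  force(cw)
  game(taxa(cw), function(members) {
    if (length(members) == 0) rq(0) else pd_clusters(cw, members)
  })
}

#' @rdname game
#' @param sw a weighted split system.
#' @export
pd_game_splits <- function(sw) {
  force(sw)
  game(taxa(sw), function(members) {
    if (length(members) == 0) rq(0) else pd_splits(sw, members)
  })
}

# ---- Shapley value ----------------------------------------------------------

exact_factorials <- function(n) {
  out <- numeric(n + 1)
  out[1] <- 1
  for (i in seq_len(n)) out[i + 1] <- out[i] * i
  rq_overflow_check(out)
  out
}

#' Shapley value of a game, by the defining sum
#'
#' Evaluates the classical coalition sum
#' SV(x) = (1/|X|!) * sum over coalitions M containing x of
#' (|M|-1)! (|X|-|M|)! (g(M) - g(M\\{x})), in exact rational arithmetic over
#' all 2^n coalitions. On the phylogenetic diversity game of a weighted
#' cluster system the result coincides exactly with the fair proportion
#' index of that weighting.
#'
#' @param g a `pd_game`.
#' @param guard maximum number of players for the exponential enumeration
#'   (default 15).
#' @return A `pdindex_index` tibble.
#' @export
shapley <- function(g, guard = 15) {
  tx <- g$taxa
  n <- length(tx)
  if (n > guard) stop("shapley() enumeration guarded at ", guard, " taxa", call. = FALSE)
  fact <- exact_factorials(n)
  nmask <- 2^n
  gvals <- vctrs::vec_init(new_rq(), nmask)
  size <- integer(nmask)
  for (m in seq_len(nmask) - 1L) {
    bits <- which(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    size[m + 1L] <- length(bits)
    gvals[m + 1L] <- g$f(tx[bits])
  }
  vals <- vctrs::vec_init(new_rq(), n)
  for (j in seq_len(n)) {
    bit <- bitwShiftL(1L, j - 1L)
    acc <- rq(0)
    for (m in seq_len(nmask) - 1L) {
      if (bitwAnd(m, bit) != 0L) {
        sz <- size[m + 1L]
        w <- fact[sz] * fact[n - sz + 1L]  # (|M|-1)! * (n-|M|)!
        marg <- gvals[m + 1L] - gvals[bitwAnd(m, bitwNot(bit)) + 1L]
        acc <- acc + marg * rq(w)
      }
    }
    vals[j] <- acc / rq(fact[n + 1L])
  }
  new_div_index(tx, vals, "shapley")
}

#' Shapley value of a split-weighted diversity game, closed form
#'
#' For split systems the Shapley value of the phylogenetic diversity game has
#' the closed form SV(x) = sum over splits A|B with x in A of
#' |B| / (|X| * |A|) * lambda(A|B), avoiding the exponential coalition sum.
#'
#' @param sw a weighted split system.
#' @return A `pdindex_index` tibble.
#' @export
shapley_splits <- function(sw) {
  tx <- taxa(sw)
  n <- rq(length(tx))
  vals <- vctrs::vec_init(new_rq(), length(tx))
  for (j in seq_along(tx)) {
    acc <- rq(0)
    for (i in seq_len(nrow(sw))) {
      in_a <- tx[j] %in% sw$side_a[[i]]
      asz <- if (in_a) sw$size_a[i] else sw$size_b[i]
      bsz <- if (in_a) sw$size_b[i] else sw$size_a[i]
      acc <- acc + sw$weight[i] * rq(bsz) / (n * rq(asz))
    }
    vals[j] <- acc
  }
  new_div_index(tx, vals, "shapley_splits")
}

# ---- structure of the PD game space ----------------------------------------

#' Dimension of the space of diversity games of a cluster system
#'
#' The games PD_omega obtained from all weightings of a cluster system span a
#' linear subspace of the space of all games whose dimension equals the
#' number of clusters: the indicator games g_C are linearly independent.
#' Computed as the exact rank of the |C| x (2^n - 1) matrix of indicator
#' games over the non-empty coalitions.
#'
#' @param cs a cluster system.
#' @param guard maximum number of taxa (default 12).
#' @return Integer rank.
#' @export
pd_space_dimension <- function(cs, guard = 12) {
  tx <- taxa(cs)
  n <- length(tx)
  if (n > guard) stop("pd_space_dimension() guarded at ", guard, " taxa", call. = FALSE)
  nmask <- 2^n - 1L
  a <- matrix(0, nrow(cs), nmask)
  for (i in seq_len(nrow(cs))) {
    cmask <- sum(bitwShiftL(1L, match(cs$cluster[[i]], tx) - 1L))
    a[i, ] <- as.integer(bitwAnd(seq_len(nmask), cmask) != 0L)
  }
  rqm_rank(rq_matrix(a))
}

#' Pareto efficiency of an index vector against a game
#'
#' Checks exactly that the index values sum to the value of the grand
#' coalition, g(X) — the efficiency axiom of the Shapley value, and the
#' game-side counterpart of completeness.
#'
#' @param index a `pdindex_index`.
#' @param g a `pd_game` on the same taxa.
#' @return `TRUE` or `FALSE`.
#' @export
check_pareto <- function(index, g) {
  if (!setequal(index$taxon, g$taxa)) stop("index and game taxa differ", call. = FALSE)
  isTRUE(rq_sum(index$value) == g$f(g$taxa))
}
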