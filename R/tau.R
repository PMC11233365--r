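# ---- split weighting -> cluster weighting maps ------------------------------

# aggregate per-part contributions into a weighted cluster system on C(S)
accumulate_cluster_weights <- function(sides, contribs, tx) {
  keys <- vapply(sides, cluster_key, "")
  ukeys <- unique(keys)
  w <- vctrs::vec_init(new_rq(), length(ukeys))
  for (i in seq_along(ukeys)) w[i] <- rq_sum(contribs[keys == ukeys[i]])
  cluster_system(lapply(ukeys, function(k) strsplit(k, ",", fixed = TRUE)[[1]]),
                 weights = w, taxa = tx)
}

#' Shapley-compatible map from split weightings to cluster weightings
#'
#' Sends a split weighting lambda to the cluster weighting on C(S) in which a
#' split A|B contributes |B|/|X| of its weight to A and |A|/|X| to B. When a
#' cluster is a part of several splits the contributions add, making the map
#' linear. Composing the fair proportion index with this map reproduces the
#' Shapley value of the split diversity game exactly.
#'
#' @param sw a weighted split system.
#' @return A weighted cluster system on the same taxa.
#' @export
tau_shapley <- function(sw) {
  n <- rq(length(taxa(sw)))
  k <- nrow(sw)
  contribs <- vctrs::vec_init(new_rq(), 2 * k)
  for (i in seq_len(k)) {
    contribs[i] <- sw$weight[i] * rq(sw$size_b[i]) / n        # part A
    contribs[k + i] <- sw$weight[i] * rq(sw$size_a[i]) / n    # part B
  }
  accumulate_cluster_weights(c(sw$side_a, sw$side_b), contribs, taxa(sw))
}

#' Even (or p-weighted) map from split weightings to cluster weightings
#'
#' Distributes the weight of each split A|B onto its two parts: a fraction p
#' to the canonical first part A (the one containing the lexicographically
#' smallest taxon) and 1-p to B; contributions over shared parts add. Any
#' 0 < p < 1 preserves completeness of a lifted index, with p = 1/2 the even
#' choice that yields the unrooted fair proportion index when composed with
#' the cluster fair proportion.
#'
#' @param sw a weighted split system.
#' @param p a rational in (0, 1); accepts strings like `"1/3"`.
#' @return A weighted cluster system on the same taxa.
#' @export
tau_half <- function(sw, p = "1/2") {
  p <- as_rq(p)
  if (!(p > rq(0) && p < rq(1))) stop("p must lie strictly between 0 and 1", call. = FALSE)
  k <- nrow(sw)
  contribs <- vctrs::vec_init(new_rq(), 2 * k)
  for (i in seq_len(k)) {
    contribs[i] <- sw$weight[i] * p
    contribs[k + i] <- sw$weight[i] * (rq(1) - p)
  }
  accumulate_cluster_weights(c(sw$side_a, sw$side_b), contribs, taxa(sw))
}

#' Lift a cluster-based index to a split system
#'
#' Evaluates Psi(lambda) = Phi(tau(lambda)): the split weighting is first
#' translated into a weighting of the induced cluster system C(S) by the
#' chosen map, then the cluster-based index is applied. With the
#' Shapley-compatible map and the fair proportion index this equals the
#' split Shapley value; with the even map it yields the unrooted fair
#' proportion (for `index = "fair_proportion"`) or a split-based equal
#' splits index (for `index = "equal_splits"`), both complete.
#'
#' @param sw a weighted split system.
#' @param index `"fair_proportion"` or `"equal_splits"`.
#' @param tau `"shapley"` (the |B|/|X| map) or `"half"` (the p / 1-p map).
#' @param p passed to [tau_half()] when `tau = "half"`.
#' @return A `pdindex_index` tibble.
#' @export
lift_index <- function(sw, index = c("fair_proportion", "equal_splits"),
                       tau = c("half", "shapley"), p = "1/2") {
  index <- match.arg(index)
  tau <- match.arg(tau)
  cw <- if (tau == "shapley") tau_shapley(sw) else tau_half(sw, p)
  out <- if (index == "fair_proportion") fair_proportion(cw) else equal_splits(cw)
  attr(out, "index") <- paste0(index, " ∘ tau_", tau)
  out
}

#' Unrooted fair proportion index, closed form
#'
#' FP_u(x) = sum over splits A|B with x in A of lambda(A|B) / (2|A|), where A
#' is the part containing x. This is the direct closed form of the fair
#' proportion index lifted through the even map, and the two computations
#' agree exactly.
#'
#' @param sw a weighted split system.
#' @return A `pdindex_index` tibble.
#' @examples
#' unrooted_fair_proportion(example_split_weighting())
#' @export
unrooted_fair_proportion <- function(sw) {
  tx <- taxa(sw)
  vals <- vctrs::vec_init(new_rq(), length(tx))
  for (j in seq_along(tx)) {
    acc <- rq(0)
    for (i in seq_len(nrow(sw))) {
      asz <- if (tx[j] %in% sw$side_a[[i]]) sw$size_a[i] else sw$size_b[i]
      acc <- acc + sw$weight[i] / rq(2 * asz)
    }
    vals[j] <- acc
  }
  new_div_index(tx, vals, "unrooted_fair_proportion")
}
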