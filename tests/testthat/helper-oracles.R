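# Independent oracles used to cross-check the package's computations.

# Shapley value as the average marginal contribution over all n! player
# orderings -- an independent definition of the value, evaluated with a
# memoised game table over subset bitmasks.
shapley_permutation_oracle <- function(g) {
  tx <- g$taxa
  n <- length(tx)
  stopifnot(n <= 6)
  gvals <- vector("list", 2^n)
  eval_mask <- function(mask) {
    if (is.null(gvals[[mask + 1]])) {
      bits <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
      gvals[[mask + 1]] <<- g$f(tx[bits])
    }
    gvals[[mask + 1]]
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (r in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], r)
    out
  }
  acc <- rep(list(rq(0)), n)
  all_orders <- perms(seq_len(n))
  for (ord in all_orders) {
    mask <- 0L
    for (j in ord) {
      before <- eval_mask(mask)
      mask <- bitwOr(mask, bitwShiftL(1L, j - 1L))
      acc[[j]] <- acc[[j]] + (eval_mask(mask) - before)
    }
  }
  vals <- vctrs::vec_c(!!!lapply(acc, function(a) a / rq(length(all_orders))))
  tibble::tibble(taxon = tx, value = vals)
}

# Fair proportion recomputed in plain double arithmetic straight from the
# definition, for tolerance-based cross-checks of the exact path.
fp_double_oracle <- function(cw) {
  tx <- taxa(cw)
  w <- as.double(cw$weight)
  vapply(tx, function(x) {
    inC <- vapply(cw$cluster, function(m) x %in% m, TRUE)
    sum(w[inC] / cw$size[inC])
  }, 1)
}

expect_rq_equal <- function(x, y) {
  x <- as_rq(x)
  y <- as_rq(y)
  expect_identical(format(x), format(y))
}
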