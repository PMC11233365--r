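test_that("fair proportion reproduces the worked five-taxon example", {
  fp <- fair_proportion(example_cluster_weighting())
  expect_identical(format(fp$value), c("5", "4", "7", "3", "6"))
  expect_rq_equal(index_value(fp, "e"), rq(6))
  expect_rq_equal(rq_sum(fp$value), rq(25))
})

test_that("fair proportion of a single weighted cluster is concentrated", {
  cw <- cluster_system(list("x", "y"), weights = c(5, 0))
  fp <- fair_proportion(cw)
  expect_rq_equal(index_value(fp, "x"), rq(5))
  expect_rq_equal(index_value(fp, "y"), rq(0))
})

test_that("fair proportion is linear and complete on random systems", {
  for (seed in 1:10) {
    cs <- random_cluster_system(5, 6, seed)
    w1 <- random_weighting(cs, seed + 100, negative = 0.3)
    w2 <- random_weighting(cs, seed + 200, negative = 0.3)
    both <- set_weights(cs, w1$weight + w2$weight)
    expect_identical(format(fair_proportion(both)$value),
                     format(fair_proportion(w1)$value + fair_proportion(w2)$value))
    scaled <- set_weights(cs, w1$weight * rq(-7, 3))
    expect_identical(format(fair_proportion(scaled)$value),
                     format(fair_proportion(w1)$value * rq(-7, 3)))
    expect_rq_equal(rq_sum(fair_proportion(w1)$value), total_weight(w1))
    # double-precision oracle within tolerance
    expect_equal(as.double(fair_proportion(w1)$value), unname(fp_double_oracle(w1)),
                 tolerance = 1e-12)
  }
})

test_that("index matrix reproduces the summation route exactly", {
  cw <- example_cluster_weighting()
  gm <- index_matrix(cw, "fair_proportion")
  row <- rqm_row(gm$gamma, match("c,d,e", gm$rows))
  expect_identical(format(row), c("0", "0", "1/3", "1/3", "1/3"))
  expect_identical(format(apply_index_matrix(gm)$value),
                   format(fair_proportion(cw)$value))
  for (seed in 1:5) {
    cs <- random_cluster_system(6, 8, seed)
    w <- random_weighting(cs, seed + 10, negative = 0.2)
    gm <- index_matrix(cs, "fair_proportion")
    expect_identical(format(apply_index_matrix(gm, w)$value),
                     format(fair_proportion(w)$value))
  }
})

test_that("equal splits coefficients follow the recursion", {
  m <- equal_splits_coefficients(example_overlapping_clusters())
  x_row <- match("a,b,c,d,e", rownames(m$n))
  expect_rq_equal(rqm_entry(m, x_row, 5), rq(1, 3))  # e is uncovered in X
  # childless cluster: coefficient 1/|C| for members
  cde <- equal_splits_coefficients(example_cluster_weighting())
  r <- match("c,d,e", rownames(cde$n))
  expect_identical(format(rqm_row(cde, r)), c("0", "0", "1/2", "1/4", "1/4"))
  childless <- equal_splits_coefficients(cluster_system(list(c("a", "b", "c"))))
  expect_identical(format(rqm_row(childless, 1)), c("1/3", "1/3", "1/3"))
})

test_that("equal splits coefficient rows always sum to one", {
  for (seed in 1:10) {
    cs <- random_cluster_system(6 + seed %% 3, 9, seed)
    rs <- rqm_row_sums(equal_splits_coefficients(cs))
    expect_true(all(rq_num(rs) == 1 & rq_den(rs) == 1))
  }
})

test_that("equal splits index reproduces the worked example and is complete", {
  es <- equal_splits(example_cluster_weighting())
  expect_identical(format(es$value), c("5", "4", "15/2", "11/4", "23/4"))
  expect_rq_equal(rq_sum(es$value), rq(25))
  # one cluster only: equal splits equals fair proportion
  one <- cluster_system(list(c("a", "b", "c")), weights = 6)
  expect_identical(format(equal_splits(one)$value), format(fair_proportion(one)$value))
  for (seed in 1:5) {
    cs <- random_cluster_system(5, 7, seed)
    w <- random_weighting(cs, seed + 50, negative = 0.2)
    expect_rq_equal(rq_sum(equal_splits(w)$value), total_weight(w))
  }
})

test_that("restriction removes one cluster and shifts FP by omega(C)/|C|", {
  cw <- example_cluster_weighting()
  res <- restrict(cw, c("c", "d", "e"))
  expect_identical(nrow(res), 7L)
  expect_identical(taxa(res), taxa(cw))
  d <- fair_proportion(cw)$value - fair_proportion(res)$value
  expect_identical(format(d), c("0", "0", "1", "1", "1"))  # 3/|{c,d,e}| each
  # re-adding with weight zero restores nothing numerically
  back <- cluster_system(c(res$cluster, list(c("c", "d", "e"))),
                         weights = c(res$weight, rq(0)), taxa = taxa(cw))
  expect_identical(format(fair_proportion(back)$value),
                   format(fair_proportion(res)$value))
  expect_error(restrict(cluster_system(list("a")), "a"), "last element")
})

test_that("property report certifies FP and flags violations with witnesses", {
  gm <- index_matrix(example_cluster_weighting(), "fair_proportion")
  pr <- check_properties(gm)
  expect_true(pr$complete && pr$nonnegative && pr$neutrality && pr$descendant_diversity)
  bad <- custom_index_matrix(
    cluster_system(list(c("a", "b"))),
    as_rq(c("1", "1"))
  )
  prb <- check_properties(bad)
  expect_false(prb$complete)
  expect_match(prb$notes, "sums to 2", all = FALSE)
})

test_that("a matrix can pass neutrality and descendant diversity without being FP", {
  ex <- example_nonfp_matrix()
  pr <- check_properties(ex$gamma)
  expect_true(pr$complete && pr$neutrality && pr$descendant_diversity)
  fp <- index_matrix(ex$system, "fair_proportion")
  expect_false(rqm_equal(ex$gamma$gamma, fp$gamma))
  # and it is downward continuous w.r.t. its own row deletion by construction
  res <- restrict(ex$system, c("a", "b"))
  g_star <- custom_index_matrix(res, ex$gamma$gamma[-match("a,b", ex$gamma$rows), ])
  expect_true(check_downward_continuity(ex$gamma, g_star, c("a", "b")))
})

test_that("FP is downward continuous; equal splits generally is not", {
  cs <- cluster_system(list("a", c("a", "b"), c("a", "b", "c")))
  res <- restrict(cs, c("a", "b"))
  expect_true(check_downward_continuity(
    index_matrix(cs, "fair_proportion"),
    index_matrix(res, "fair_proportion"),
    c("a", "b")
  ))
  expect_false(check_downward_continuity(
    index_matrix(cs, "equal_splits"),
    index_matrix(res, "equal_splits"),
    c("a", "b")
  ))
})

test_that("overlapping systems can rank differently from their hierarchic restrictions", {
  # a constructed instance of the ranking-reversal phenomenon
  cs <- cluster_system(list(c("a", "b"), c("b", "c"), "a", "b", "c"),
                       weights = c(4, 4, 3, 0, 3))
  full_rank <- rank_taxa(fair_proportion(cs))
  res <- restrict(cs, c("a", "b"))
  sub_rank <- rank_taxa(fair_proportion(res))
  expect_false(identical(full_rank$taxon, sub_rank$taxon))
})
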