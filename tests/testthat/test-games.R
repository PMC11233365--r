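test_that("phylogenetic diversity of subsets follows the cluster definition", {
  cw <- example_cluster_weighting()
  expect_rq_equal(pd_clusters(cw, c("a", "b", "d")), rq(15))
  expect_rq_equal(pd_clusters(cw, character(0)), rq(0))
  expect_rq_equal(pd_clusters(cw, taxa(cw)), rq(25))
  expect_error(pd_clusters(cw, "z"), "unknown taxa")
})

test_that("split diversity counts only splits separated within the subset", {
  sw <- example_split_weighting()
  expect_rq_equal(pd_splits(sw, "a"), rq(0))
  expect_rq_equal(pd_splits(sw, character(0)), rq(0))
  expect_rq_equal(pd_splits(sw, taxa(sw)), rq(25))
  # splits separating a from e: the two trivial ones plus ab|cde and de|abc
  expect_rq_equal(pd_splits(sw, c("a", "e")), rq(16))
})

test_that("unit games span the diversity game", {
  tx <- letters[1:4]
  ga <- unit_game(tx, "a")
  expect_rq_equal(game_value(ga, c("a", "b")), rq(1))
  expect_rq_equal(game_value(ga, "b"), rq(0))
  gx <- unit_game(tx, tx)
  expect_rq_equal(game_value(gx, "c"), rq(1))
  expect_error(game(tx, function(m) 1), "empty coalition")
  # PD_omega(M) = sum over clusters of omega(C) * g_C(M), all subsets, n = 4
  cs <- random_cluster_system(4, 5, 7)
  w <- random_weighting(cs, 8)
  pg <- pd_game(w)
  units <- lapply(w$cluster, function(cl) unit_game(taxa(w), cl))
  masks <- 0:(2^4 - 1)
  for (m in masks) {
    members <- taxa(w)[bitwAnd(m, bitwShiftL(1L, 1:4 - 1L)) != 0L]
    span <- rq(0)
    for (i in seq_along(units)) {
      span <- span + w$weight[i] * game_value(units[[i]], members)
    }
    expect_rq_equal(game_value(pg, members), span)
  }
})

test_that("the Shapley value of the diversity game equals fair proportion", {
  cw <- example_cluster_weighting()
  sv <- shapley(pd_game(cw))
  expect_identical(format(sv$value), c("5", "4", "7", "3", "6"))
  for (seed in 1:5) {
    cs <- random_cluster_system(5, 6, seed)
    w <- random_weighting(cs, seed + 30, negative = 0.2)
    expect_identical(format(shapley(pd_game(w))$value),
                     format(fair_proportion(w)$value))
  }
})

test_that("the coalition-sum Shapley value matches the permutation average", {
  for (seed in 1:3) {
    cs <- random_cluster_system(4, 4, seed)
    w <- random_weighting(cs, seed + 60)
    g <- pd_game(w)
    expect_identical(format(shapley(g)$value),
                     format(shapley_permutation_oracle(g)$value))
  }
})

test_that("the Shapley value is group proportional and additive", {
  tx <- letters[1:5]
  g <- unit_game(tx, c("b", "d", "e"))
  scaled <- game(tx, function(m) game_value(g, m) * rq(6))
  sv <- shapley(scaled)
  expect_identical(format(sv$value), c("0", "2", "0", "2", "2"))
  # additivity over games
  g2 <- unit_game(tx, c("a", "b"))
  both <- game(tx, function(m) game_value(g, m) + game_value(g2, m))
  expect_identical(format(shapley(both)$value),
                   format(shapley(g)$value + shapley(g2)$value))
  # one player takes the whole singleton value
  solo <- game("a", function(m) if (length(m) > 0) rq(9, 2) else rq(0))
  expect_rq_equal(shapley(solo)$value, rq(9, 2))
})

test_that("the split closed form agrees with the brute-force Shapley value", {
  sw <- example_split_weighting()
  sv <- shapley_splits(sw)
  expect_rq_equal(index_value(sv, "e"), rq(16, 3))
  one <- split_system(list("a"), weights = 5, taxa = letters[1:5])
  expect_identical(format(shapley_splits(one)$value),
                   c("4", "1/4", "1/4", "1/4", "1/4"))
  for (seed in 1:4) {
    ss <- random_circular_split_system(5, 6, seed)
    w <- random_weighting(ss, seed + 40)
    expect_identical(format(shapley_splits(w)$value),
                     format(shapley(pd_game_splits(w))$value))
  }
})

test_that("the diversity game space has dimension equal to the cluster count", {
  expect_identical(pd_space_dimension(example_cluster_weighting()), 8L)
  expect_identical(pd_space_dimension(cluster_system(list(c("a", "b")))), 1L)
  # the full power set has full rank
  pow3 <- cluster_system(lapply(1:7, function(m) {
    letters[1:3][bitwAnd(m, c(1L, 2L, 4L)) != 0L]
  }))
  expect_identical(pd_space_dimension(pow3), 7L)
  for (seed in 1:5) {
    cs <- random_cluster_system(5, 6, seed)
    expect_identical(pd_space_dimension(cs), nrow(cs))
  }
})

test_that("the Shapley value is Pareto efficient", {
  cw <- example_cluster_weighting()
  g <- pd_game(cw)
  expect_true(check_pareto(shapley(g), g))
  expect_true(check_pareto(fair_proportion(cw), g))
  zero <- game(letters[1:3], function(m) rq(0))
  expect_true(check_pareto(shapley(zero), zero))
})
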