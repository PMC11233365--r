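test_that("the full circular system enumerates all interval splits", {
  th4 <- letters[1:4]
  full <- full_circular_system(th4)
  expect_setequal(full$label, c("a|b,c,d", "a,b|c,d", "a,b,c|d",
                                "a,c,d|b", "a,d|b,c", "a,b,d|c"))
  for (n in 3:8) {
    expect_identical(nrow(full_circular_system(letters[1:n])),
                     as.integer(n * (n - 1) / 2))
  }
  full5 <- full_circular_system(letters[1:5])
  expect_true(is_circular(full5, letters[1:5]))
  expect_error(full_circular_system(c("a", "b")), "at least 3")
})

test_that("the pair incidence matrix records separated pairs", {
  ss <- split_system(list("a"), taxa = letters[1:4])
  m <- pair_incidence(ss)
  expect_identical(as.vector(m$n[1, ]), c(1, 1, 1, 0, 0, 0))  # a,b a,c a,d then rest
  full <- full_circular_system(letters[1:4])
  mf <- pair_incidence(full)
  expect_identical(dim(mf), c(6L, 6L))
  expect_identical(rqm_rank(mf), 6L)
  for (seed in 1:5) {
    ss <- random_circular_split_system(5 + seed %% 3, 7, seed)
    expect_identical(rqm_rank(pair_incidence(ss)), nrow(ss))
  }
})

test_that("induced distances sum the weights of separating splits", {
  sw <- example_split_weighting()
  d <- split_distances(sw)
  expect_rq_equal(d$distance[d$x == "a" & d$y == "e"], rq(16))
  zero <- split_distances(set_weights(sw, 0))
  expect_true(all(rq_num(zero$distance) == 0))
  # distinct weightings of a circular system give distinct distances
  th <- letters[1:5]
  base <- full_circular_system(th)
  d1 <- split_distances(set_weights(base, rq(1:10)))
  d2 <- split_distances(set_weights(base, rq(c(2, 1:9))))
  expect_false(identical(format(d1$distance), format(d2$distance)))
})

test_that("the closed-form right inverse is validated and sparse", {
  for (n in 4:6) {
    ri <- full_right_inverse(letters[1:n])  # construction asserts M R = I
    nz_per_col <- colSums(ri$r$n != 0)
    expect_true(all(nz_per_col <= 4))
    vals <- abs(ri$r$n[ri$r$n != 0] / ri$r$d[ri$r$n != 0])
    expect_true(all(vals == 0.5))
  }
  # uniqueness: the closed form equals explicit exact inversion
  for (n in 4:5) {
    full <- full_circular_system(letters[1:n])
    expect_true(rqm_equal(full_right_inverse(letters[1:n])$r,
                          rqm_inverse(pair_incidence(full))))
  }
})

test_that("psi_R is complete and its two evaluation routes agree", {
  th <- letters[1:5]
  ri <- full_right_inverse(th)
  base <- full_circular_system(th)
  for (seed in 1:4) {
    w <- random_weighting(base, seed + 130, negative = 0.2)
    attr(w, "ordering") <- th
    v <- psi_r(w, ri)
    expect_rq_equal(rq_sum(v$value), total_weight(w))
    gm <- psi_r_matrix(base, ri)
    expect_identical(format(apply_index_matrix(gm, w)$value), format(v$value))
  }
  # concentrating the weighting on one split picks out that matrix row
  gm <- psi_r_matrix(base, ri)
  w1 <- set_weights(base, rq(as.integer(base$label == "a|b,c,d,e")) * rq(6))
  attr(w1, "ordering") <- th
  expect_identical(format(psi_r(w1, ri)$value),
                   format(rqm_row(gm$gamma, match("a|b,c,d,e", gm$rows)) * rq(6)))
})

test_that("the three-valued closed form reproduces the inverted matrix", {
  for (n in 4:6) {
    th <- letters[1:n]
    closed <- pauplin_gamma(th)
    direct <- psi_r_matrix(full_circular_system(th), full_right_inverse(th))
    expect_true(rqm_equal(closed$gamma, direct$gamma))
    rs <- rqm_row_sums(closed$gamma)
    expect_true(all(rq_num(rs) == 1 & rq_den(rs) == 1))
  }
  th <- letters[1:5]
  expect_rq_equal(pauplin_gamma_entry(th, "a", "a"), rq(1, 2))        # singleton part
  expect_rq_equal(pauplin_gamma_entry(th, c("a", "b", "c"), "a"), rq(1, 4))  # endpoint
  expect_rq_equal(pauplin_gamma_entry(th, c("a", "b", "c"), "b"), rq(0))     # interior
  expect_rq_equal(pauplin_gamma_entry(th, c("a", "b", "c"), "d"), rq(1, 4))  # complement endpoint
  expect_error(pauplin_gamma_entry(th, c("a", "c"), "a"), "not circular")
})

test_that("non-full circular systems inherit two complete indices", {
  th <- letters[1:4]
  ss <- split_system(list("a", "b", "c", "d", c("a", "b")), taxa = th)
  full <- full_circular_system(th)
  same <- restricted_psi(full, th, "gamma_rows")
  expect_true(rqm_equal(same$gamma, pauplin_gamma(th)$gamma))
  p1 <- restricted_psi(ss, th, "gamma_rows")
  p2 <- restricted_psi(ss, th, "inverse_columns")
  expect_true(check_properties(p1)$complete)
  expect_true(check_properties(p2)$complete)
  expect_false(rqm_equal(p1$gamma, p2$gamma))
  # the row-restricted and column-restricted members differ in the known way:
  # p1 is non-negative here, p2 need not be
  expect_true(all(p1$gamma$n >= 0))
  for (seed in 1:4) {
    sub <- random_circular_split_system(5, 6, seed)
    th5 <- attr(sub, "ordering")
    p2r <- restricted_psi(sub, th5, "inverse_columns")  # validates M R' = I
    expect_true(check_properties(p2r)$complete)
  }
})
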