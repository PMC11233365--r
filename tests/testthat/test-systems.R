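test_that("cluster system construction canonicalizes and validates", {
  cs <- cluster_system(list(c("a", "b"), c("c", "d", "e"), c("d", "e"),
                            "a", "b", "c", "d", "e"))
  expect_s3_class(cs, "pdindex_clusters")
  expect_identical(nrow(cs), 8L)
  expect_identical(taxa(cs), c("a", "b", "c", "d", "e"))
  # duplicates collapse under set semantics
  dup <- cluster_system(list(c("a", "b"), c("b", "a")))
  expect_identical(nrow(dup), 1L)
  # minimal system
  single <- cluster_system(list("a"))
  expect_identical(single$label, "a")
  expect_error(cluster_system(list()), "at least one")
  expect_error(cluster_system(list(character(0)), taxa = "a"), "non-empty")
  expect_error(cluster_system(list("z"), taxa = c("a", "b")), "not in the taxon set")
})

test_that("hierarchy recognition matches the nested-or-disjoint definition", {
  expect_true(is_hierarchy(example_cluster_weighting()))
  expect_false(is_hierarchy(cluster_system(list(c("a", "b"), c("b", "c")))))
  expect_true(is_hierarchy(cluster_system(list("a", "b", "c"))))
  expect_false(is_hierarchy(example_overlapping_clusters()))
})

test_that("children are the maximal proper sub-clusters", {
  cs <- example_overlapping_clusters()
  ch <- children(cs, c("a", "b", "c", "d", "e"))
  expect_setequal(vapply(ch, paste, "", collapse = ","), c("a,b,c", "c,d"))
  # a chain only yields the closest cluster
  chain <- cluster_system(list("a", c("a", "b"), c("a", "b", "c")))
  expect_identical(children(chain, c("a", "b", "c")), list(c("a", "b")))
  expect_identical(children(chain, "a"), list())
  expect_error(children(chain, c("b", "c")), "not in the system")
})

test_that("uncovered taxa and descendant counts follow the definitions", {
  cs <- example_overlapping_clusters()
  expect_identical(cluster_free_taxa(cs, c("a", "b", "c", "d", "e")), "e")
  expect_identical(descendant_count(cs, c("a", "b", "c", "d", "e")), 4L)
  # no children: every member is free, none descendant
  expect_identical(cluster_free_taxa(cs, c("c", "d")), c("c", "d"))
  expect_identical(descendant_count(cs, c("c", "d")), 0L)
  pair <- cluster_system(list("a", "b", c("a", "b")))
  expect_identical(cluster_free_taxa(pair, c("a", "b")), character(0))
  expect_identical(descendant_count(pair, c("a", "b")), 2L)
})

test_that("descendant count equals the union of children by enumeration", {
  for (seed in 1:10) {
    cs <- random_cluster_system(5, 8, seed)
    for (i in seq_len(nrow(cs))) {
      expect_identical(descendant_count(cs, cs$cluster[[i]]),
                       length(unique(unlist(children(cs, cs$cluster[[i]])))))
    }
  }
})

test_that("split canonical form and compatibility behave", {
  ss <- split_system(list(c("c", "d", "e")), taxa = letters[1:5])
  expect_identical(ss$label, "a,b|c,d,e")
  expect_true(is_compatible(example_split_weighting()))
  quartet <- split_system(list(c("a", "b"), c("a", "c")), taxa = letters[1:4])
  expect_false(is_compatible(quartet))
  trivial <- split_system(list("a", "b", "c"), taxa = letters[1:3])
  expect_true(is_compatible(trivial))
})

test_that("circularity is recognized with and without a given ordering", {
  th <- letters[1:5]
  full <- full_circular_system(th)
  expect_true(is_circular(full, th))
  expect_true(is_circular(example_split_weighting(), th))
  ss <- split_system(list(c("a", "b")), taxa = letters[1:5])
  expect_false(is_circular(ss, c("a", "c", "b", "d", "e")))
  found <- is_circular(ss)
  expect_true(isTRUE(found))
  expect_true(is_circular_with <- is_circular(ss, attr(found, "ordering")))
  expect_error(is_circular(ss, c("a", "b")), "permutation")
})

test_that("every compatible split system is circular (sampled, small n)", {
  for (seed in 1:15) {
    n <- 4 + seed %% 4  # 4..7 taxa
    ss <- random_split_system(n, 4, seed)
    mx <- maximal_compatible_subsystems(ss)[[1]]
    expect_true(isTRUE(is_circular(mx)))
  }
})

test_that("clusters_of_splits collects both parts, deduplicated", {
  ss <- split_system(list(c("a", "b")), taxa = letters[1:5])
  cs <- clusters_of_splits(ss)
  expect_setequal(cs$label, c("a,b", "c,d,e"))
  cs7 <- clusters_of_splits(example_split_weighting())
  expect_identical(nrow(cs7), 14L)  # 5 singletons, 5 four-sets, 4 others, all distinct
  expect_true(nrow(cs7) <= 2 * nrow(example_split_weighting()))
  # two splits sharing a part
  sh <- split_system(list(c("a", "b"), c("c", "d")), taxa = letters[1:4])
  expect_identical(nrow(clusters_of_splits(sh)), 2L)
})

test_that("maximal compatible subsystems are exactly the maximal cliques", {
  ss <- split_system(list(c("a", "b"), c("a", "c"), "a", "b", "c", "d"),
                     taxa = letters[1:4])
  mc <- maximal_compatible_subsystems(ss)
  expect_length(mc, 2)
  expect_true(all(vapply(mc, nrow, 1L) == 5))
  expect_true(all(vapply(mc, is_compatible, TRUE)))
  # each contains the four trivial splits plus one incompatible pair member
  for (m in mc) expect_true(all(c("a|b,c,d", "a,c,d|b", "a,b,d|c", "a,b,c|d")
                                %in% m$label))
  comp <- example_split_weighting()
  expect_length(maximal_compatible_subsystems(comp), 1)
  one <- split_system(list("a"), taxa = c("a", "b"))
  expect_identical(maximal_compatible_subsystems(one)[[1]]$label, one$label)
})

test_that("circular systems respect the n(n-1)/2 bound", {
  for (n in 3:7) {
    full <- full_circular_system(letters[1:n])
    expect_identical(nrow(full), as.integer(n * (n - 1) / 2))
  }
  for (seed in 1:5) {
    ss <- random_circular_split_system(6, 12, seed)
    expect_true(nrow(ss) <= 15)
    expect_true(is_circular(ss, attr(ss, "ordering")))
  }
})
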