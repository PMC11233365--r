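Package: pdindex
Title: Phylogenetic Diversity Indices on Cluster and Split Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact-rational computation of phylogenetic diversity indices in a
    unified affine (cluster-based) and projective (split-based) setting. Provides
    the fair proportion and equal splits indices on arbitrary weighted cluster
    systems, the Shapley value of phylogenetic diversity games, linear maps that
    translate split weightings into cluster weightings and thereby lift
    cluster-based indices to split systems, and Pauplin-type indices on circular
    split systems built from right inverses of the split-pair incidence matrix.
    Includes checkers for the structural properties (completeness, neutrality,
    descendant diversity, downward continuity, Pareto efficiency, group
    proportionality) that characterize these indices, readers and writers for
    Newick trees, tabular weighted systems and NEXUS splits blocks, and seeded
    generators for random hierarchies, cluster systems and circular split
    systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    ape,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    tibble,
    vctrs,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
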