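# pdindex

Exact computation of phylogenetic diversity indices on weighted **cluster
systems** (the rooted/affine view of a phylogeny) and weighted **split
systems** (the unrooted/projective view), for researchers in phylogenetics
and conservation prioritization who want to score species without committing
to a single, fully resolved tree.

## What it computes

For a taxon set $X$, a weighted cluster system $(\mathscr{C}, \omega)$
generalizes a rooted tree with branch lengths (one cluster per edge), and a
weighted split system $(\mathscr{S}, \lambda)$ generalizes an unrooted tree.
pdindex implements, entirely in exact rational arithmetic:

* the **fair proportion** index
  $FP(\omega)(x) = \sum_{C \ni x} \omega(C) / |C|$ and the recursive
  **equal splits** index on arbitrary cluster systems, with their
  $|\mathscr{C}| \times |X|$ index matrices $\Gamma$;
* the **phylogenetic diversity game**
  $PD_\omega(M) = \sum_{C \cap M \neq \emptyset} \omega(C)$ and its
  **Shapley value** — by the exact $2^n$ coalition sum for any game, and by
  the closed form
  $SV(x) = \sum_{A|B:\,x \in A} \tfrac{|B|}{|X|\,|A|}\, \lambda(A|B)$ for
  split systems;
* the linear maps $\tau$ from split weightings to cluster weightings that
  lift any cluster index $\Phi$ to a split index $\Phi \circ \tau$ —
  including the **unrooted fair proportion**
  $\sum_{A|B:\,x \in A} \lambda(A|B) / (2|A|)$;
* **Pauplin-type indices** $\Psi_R$ on circular split systems, built from
  right inverses of the split–pair incidence matrix $M(\mathscr{S})$, with
  the unique three-valued closed form for full circular systems;
* checkers for the structural axioms (completeness, neutrality, descendant
  diversity, downward continuity, Pareto efficiency, group proportionality)
  that characterize these indices, reported with violation witnesses;
* readers/writers for Newick trees, weighted-system TSV, NEXUS SPLITS
  blocks (SplitsTree dialect, with CYCLE), PHYLIP distance matrices and
  JSON, plus seeded random generators for hierarchies, cluster systems and
  circular split systems.

All arithmetic uses an exact rational vector class (`rq`), so identities
like "the scores sum to the total branch weight" hold exactly, not to
floating-point tolerance.

## A worked example

The five-taxon tree `((a:3,b:2):4,(c:6,(d:1,e:4):2):3);` has total branch
length 25. Scoring its clusters and splits:

```r
library(pdindex)

tree <- read_newick(example_tree_newick())
cw   <- tree_to_clusters(tree)     # 8 weighted clusters
fair_proportion(cw)
#> # Diversity index <fair_proportion> on 5 taxa (total 25)
#> # A tibble: 5 × 2
#>   taxon value
#>   <chr>  <rq>
#> 1 a         5
#> 2 b         4
#> 3 c         7
#> 4 d         3
#> 5 e         6
```

Taxon `c` is the most distinctive (score 7): it sits alone on a long branch.
The scores sum to 25, the total branch length — fair proportion is
*complete*. The Shapley value of the diversity game returns the same vector,
`shapley(pd_game(cw))`, reflecting the exact coincidence of the two indices
on cluster systems. Unrooting the tree and scoring splits instead:

```r
sw <- tree_to_splits(tree)         # 7 weighted splits; root edges merge to 7
unrooted_fair_proportion(sw)$value
#> <pdindex_rq[5]>
#> [1] 125/24 29/6   23/4   97/24  31/6
pd_clusters(cw, c("a", "b", "d"))  # Faith's PD of a candidate set
#> <pdindex_rq[1]>
#> [1] 15
```

Note the exact fractions: taxon `e` scores 31/6 unrooted. Rankings,
doubles and plots come from the broom-style helpers: `tidy()`, `glance()`,
`rank_taxa()`, `autoplot()`.

A thin command-line interface over the same functions ships in
`inst/cli/pdindex.R`:

```sh
Rscript inst/cli/pdindex.R fp --tree example_tree.nwk
Rscript inst/cli/pdindex.R psi-tau --splits splits.tsv --index equal_splits --p 1/2
```

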