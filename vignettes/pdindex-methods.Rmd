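---
title: "Diversity indices on clusters and splits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity indices on clusters and splits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdindex)
```

## The setting

Phylogenetic diversity indices score each species in a set $X$ by how much
unique and shared evolutionary history it represents, and are widely used to
rank species for conservation. Classically the history is a rooted tree with
branch lengths (the *affine* view: each edge contributes the cluster of
leaves below it) or an unrooted tree (the *projective* view: each edge
contributes a bipartition, or split, of $X$). pdindex works one level up, on
arbitrary **weighted cluster systems** $(\mathscr{C}, \omega)$ and **weighted
split systems** $(\mathscr{S}, \lambda)$, so that trees, split networks,
circular split systems and overlapping cluster collections are all handled by
the same machinery. That generality matters in practice when the tree
topology is uncertain: one can score species directly on the (possibly
incompatible) collection of supported clades or splits instead of committing
to one tree.

A *phylogenetic diversity index* here is a map from weightings to vectors in
$\mathbb{R}^X$. The ones computed by the package:

* **Fair proportion** (`fair_proportion()`):
  $FP(\omega)(x) = \sum_{C \ni x} \omega(C)/|C|$ — each cluster's weight is
  shared equally among its members.
* **Equal splits** (`equal_splits()`): each cluster splits its weight into
  $|ch(C)| + |cl(C)|$ equal shares, one per child cluster and one per member
  covered by no child, recursively. On rooted binary trees this is the
  classical equal-splits score.
* **Shapley value** (`shapley()`, `shapley_splits()`): the game-theoretic
  value of the diversity game $PD_\omega(M) = \sum_{C \cap M \ne \emptyset}
  \omega(C)$ (or its split analogue). On diversity games of cluster systems
  the Shapley value *equals* fair proportion, which the test suite asserts
  exactly on random systems.
* **Pauplin-type indices** (`psi_r()`, `pauplin_gamma()`,
  `restricted_psi()`): on a circular split system, any right inverse $R$ of
  the split–pair incidence matrix $M(\mathscr{S})$ yields a complete linear
  index $\Psi_R$; for a full circular system $R$ is the unique inverse and
  the index matrix collapses to a three-valued closed form (entries $1/2$,
  $1/4$, $0$ by the position of the taxon in the split's cyclic interval).

The two views are bridged by linear maps $\tau$ from split weightings to
weightings of the induced cluster system $\mathscr{C}(\mathscr{S})$
(`tau_shapley()`, `tau_half()`); `lift_index()` computes
$\Psi(\lambda) = \Phi(\tau(\lambda))$. With the $|B|/|X|$ map, lifting fair
proportion reproduces the split Shapley value; with the even map it
reproduces the unrooted fair proportion closed form
$\sum_{A|B:\, x \in A} \lambda(A|B)/(2|A|)$.

## Why exact rational arithmetic

The defining identities of these indices are *exact*: completeness says the
scores sum to precisely the total weight, the Shapley/fair-proportion
coincidence is an equality of rationals, and $M(\mathscr{S}) \cdot R = I$ is
an identity of matrices. In floating point all of these hold only to
tolerance, and property checkers (is this matrix complete? is this candidate
$R$ a right inverse?) would need arbitrary thresholds. The package therefore
carries a small vctrs-backed rational class (`rq`) through every computation:
numerators and denominators are doubles restricted to the exactly
representable integer range, and any intermediate value that would exceed
$2^{53}$ raises an error rather than rounding. At the problem sizes the
package targets (tens of taxa for the linear indices; the exponential Shapley
enumeration is guarded at 15 taxa, the exact rank computation at 12) the
factorials and products involved stay far inside that range. Matrix ranks and
inverses use fraction-based Gauss–Jordan elimination with the first non-zero
pivot; with exact arithmetic, pivot choice affects only speed, never
correctness.

## Tunable parameters

* `p` in `tau_half()` — the fraction of a split's weight assigned to its
  canonical first part (the one containing the lexicographically smallest
  taxon); dimensionless, default $1/2$. Any $0 < p < 1$ preserves
  completeness of the lifted index; $1/2$ is the symmetric choice that
  recovers the unrooted fair proportion and is the only choice that does not
  depend on the storage convention for splits.
* `guard` in `shapley()` (default 15) and `pd_space_dimension()` (default
  12) — hard caps on the exponential enumerations, chosen so that the
  factorial weights and the $2^n$ subset table remain exact and affordable.
* `method` in `restricted_psi()` — for circular systems that are not full,
  the two canonical members of the $\Psi_R$ family: restricting the
  closed-form index matrix by rows, or restricting the unique full-system
  right inverse by columns (re-validated as a right inverse). Both are
  complete; they generally differ, and only the row restriction is
  guaranteed non-negative.

## Conventions and degenerate inputs

* Taxa are kept in lexicographic order; that order fixes every matrix row
  and column, vector order, and the canonical form of a split (part with the
  smallest taxon first). File round trips are therefore byte-stable.
* A cluster or split with weight 0 is still a structural member of its
  system: children, equal-splits coefficients and property checks see it.
  Removing an element is the explicit `restrict()` operation, after which
  recursive structure (children, coefficients) is recomputed from scratch —
  which is exactly why equal splits fails downward continuity while fair
  proportion satisfies it.
* Duplicate clusters or splits in input are merged; their weights are
  summed, with a warning when the duplicates carried non-zero weight.
  Suppressing a degree-2 root while unrooting a tree uses the same merge
  silently, since it is the expected behaviour, not a data problem.
* The equal-splits recursion is applied verbatim on non-hierarchies:
  overlapping children each contribute their share, with no renormalization;
  the row-sum-1 identity still holds, which the tests assert on random
  overlapping systems.
* Branch lengths read from Newick are converted to rationals through their
  decimal representation (15 significant digits, scientific notation
  accepted); integer and short-decimal lengths are therefore exact. A
  missing length is 0, and the edge still contributes its cluster/split.
* Circularity testing without a supplied ordering enumerates the
  $(n-1)!/2$ cyclic orders and is refused above 8 taxa; general circular
  recognition is out of scope. `maximal_compatible_subsystems()` enumerates
  maximal cliques of the compatibility graph and is guarded at 20 splits.
* The closed-form right inverse of a full circular system is constructed
  from its sparse $\pm 1/2$ pattern and then *verified* against
  $M \cdot R = I$ exactly; an index-convention mistake fails loudly instead
  of propagating.

## What the generators emulate

The seeded generators (`random_hierarchy()`, `random_cluster_system()`,
`random_split_system()`, `random_circular_split_system()`,
`random_weighting()`) produce the inputs for the property-based tests:
hierarchies arise by random binary agglomeration (mimicking a random tree
shape), cluster/split systems are uniform over distinct subsets or splits,
and weights are small rationals $\pm p/q$ with numerators up to 9 and
denominators in $\{1,2,3,4,6\}$, optionally negative — the theory places no
sign restriction, and the tests deliberately exercise negative weights.
These inputs probe *algebraic identities*, which hold for every weighting,
so nothing about realistic branch-length distributions, rate variation or
taxon sampling is (or needs to be) emulated; passing tests certify the
combinatorics and algebra, not any statistical behaviour on empirical data.
The test suite and acceptance checks run the identity-based properties on
systems of 3–7 taxa (about a hundred random systems per identity, plus full
circular systems for 4–7 taxa), sizes at which the exponential brute-force
oracles — the $2^n$ coalition sum, the $n!$ permutation average for the
Shapley value and full matrix inversion — remain exact and fast.

## Design choices that were genuinely open

* **Tidy surface.** Systems are tibble subclasses with list-columns of
  members and an exact rational weight column; index vectors are tibbles
  with `tidy()`, `glance()`, `autoplot()` and `rank_taxa()` methods. The
  exact values live in the `value`/`weight` columns; `tidy()` adds doubles
  for plotting and ranking.
* **Games carry an evaluator, not a table.** `shapley()` materializes the
  $2^n$ values lazily from the game's function, so user-defined games work;
  membership of a game in the diversity-game span is available separately as
  the exact rank test `pd_space_dimension()`. The Shapley formula is applied
  to whatever game is supplied — it is defined for all games — rather than
  erroring outside the span.
* **Downward continuity is checked structurally** (row deletion of the index
  matrix) rather than by numeric limits: for linear indices the two are
  equivalent, and the structural check is exact.
* **Right inverses beyond the two canonical constructions** are accepted
  from the user through `right_inverse()`, validated exactly; the full
  affine family of right inverses of a non-full system is not parametrized
  symbolically.
* **The five-taxon worked example** is reconstructed from its printed
  arithmetic (cluster weights, split weights, index values, total 25) and
  shipped as `example_*()` fixtures; the acceptance script re-derives it
  from the Newick string end to end.

## Limitations

* Everything is exact but dense and interpreted: the intended scale is
  combinatorial examples and simulation studies up to tens of taxa, not
  genome-scale trees. For fixed trees at scale, specialised tree traversals
  (e.g. in picante) are the right tool for fair proportion in doubles.
* Only the split-to-cluster direction of the affine–projective bridge is
  implemented; maps from cluster systems to split systems, weak hierarchies
  and general phylogenetic networks are out of scope.
* Non-circular linearly independent split systems are not handled by the
  $\Psi_R$ machinery (their right inverses exist but the circular closed
  form does not apply).
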