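---
title: "Multifurcating neighbor joining: method, tuning, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifurcating neighbor joining: method, tuning, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfnj)
```

## The problem

Neighbor joining (NJ) is the standard distance-based method for
reconstructing phylogenetic trees: starting from a matrix $D_{ij}$ of
pairwise evolutionary distances over $N$ operational taxonomic units
(OTUs), it repeatedly joins the pair minimizing the Studier–Keppler
criterion

$$S_{ij} = (N-2)\,D_{ij} - R_i - R_j, \qquad R_i = \sum_k D_{ik},$$

replaces the pair by a new internal node, and shrinks the matrix by one.
Minimizing $S$ is equivalent to minimizing the total branch length of the
resulting tree.

Because NJ can only create bifurcations, it must pick a *single* pair even
when several pairs attain the minimal $S$ exactly — the *ties in
proximity* problem. Which tied pair a given implementation picks usually
depends on the order of the taxa in the input file, so two researchers
running the same data through the same program can publish different
trees. This package implements the multifurcating generalization (MFNJ):
when ties occur, the whole tied group is joined at once into a single
polytomic node, and disjoint tied groups are joined simultaneously in the
same iteration. The output is unique and independent of input order; on
tie-free iterations it coincides with classic NJ.

## The generalized formulas

Let $I$ be a set of $|I| \ge 2$ OTUs to be joined into a new node $u$.
With $R_{II}$ the sum of distances over unordered pairs inside $I$,
$R_{Ik}$ the total distance from $I$ to an outside OTU $k$, and $R_{IJ}$
the total cross-distance between two disjoint join sets $I$ and $J$:

* distance from the new node to an outside OTU:
  $D_{uk} = R_{Ik}/|I| - R_{II}/(|I|(|I|-1))$;
* distance between two nodes created in the same iteration:
  $D_{uv} = R_{IJ}/(|I||J|) - R_{II}/(|I|(|I|-1)) - R_{JJ}/(|J|(|J|-1))$;
* branch lengths when at least one active OTU remains outside $I$
  (the complement $I^\complement$ of $I$ among the $N$ active OTUs,
  *including* members of sibling join sets of the same iteration):
  $L_{iu} = R_{II}/(|I|(|I|-1)) + R_{iI^\complement}/(N-|I|)
            - R_{II^\complement}/(|I|(N-|I|))$;
* branch lengths of the final join, when $I$ is all remaining OTUs:
  $L_{iu} = R_{iI}/(|I|-2) - R_{II}/((|I|-1)(|I|-2))$.

For $|I| = 2$ the first and third formulas reduce *exactly* to the classic
NJ pair update and pair branch lengths, and for $|I| = 3$ the last reduces
to the familiar three-point formula
$L_{1u} = (D_{12} + D_{13} - D_{23})/2$. Both branch-length formulas
satisfy the star-tree conservation identity
$\sum_{i \in I} L_{iu} = R_{II}/(|I|-1)$, which the test suite asserts as
a runtime invariant. These reductions and the conservation identity are
exercised on 1000 random matrices in `tests/testthat/test-acceptance.R`.

## Tunable parameters

All knobs live in `mfnj_config()`:

| parameter | default | units / meaning |
|---|---|---|
| `tie_rtol` | `1e-9` | relative tolerance for "equal" $S$ values |
| `tie_atol` | `1e-12` | absolute tolerance, same units as $S$ |
| `negative_branch` | `"keep"` | or `"clamp_to_zero"` for display |
| `nj_tie_break` | `"first_scan"` | classic-NJ tie policy |
| `enum_cap` | `64` | max distinct trees from `enumerate_nj()` |
| `precision` | `6` | significant digits for Newick lengths |

**Tie tolerance.** The method is defined over exact arithmetic, where tied
$S$ values are exactly equal. In floating point, summation order perturbs
mathematically equal values by a few ulps, while genuinely distinct pairs
on data printed with one decimal (like the bundled bear matrix) differ in
$S$ by $10^{-2}$ or more. A pair is therefore tied with the minimum when
$S \le S_{\min} + \texttt{tie\_atol} + \texttt{tie\_rtol}\,|S_{\min}|$;
the defaults sit many orders of magnitude from both regimes. Whether
input-order invariance survives *near*-ties that straddle the tolerance
boundary is data-dependent and is only asserted for exact-decimal inputs.

**Negative branch lengths** arise from the same arithmetic as in classic
NJ (the bear tree gives Grizzly $-0.02$) and are kept by default.
Clamping, when requested, happens after the whole agglomeration, so it
never changes the trajectory, only the serialized lengths.

## Design decisions

**Grouping rule.** The construction in the method's definition joins two
tied pairs sharing an OTU into one three-OTU group. We generalize by
taking the connected components of the graph whose edges are the tied
minimal pairs: chains of ties merge transitively, and a pair inside a
component is joined even if its own $S$ is not minimal (the three-OTU
construction never requires $S_{i_1 i_3} = S_{\min}$ either). Components
are joined simultaneously, each into its own node; distances between two
new nodes use the node–node formula above.

**Iteration counting** is per loop pass, 1-based, regardless of how many
groups the pass joins. On the bear matrix the tie is found at iteration 5,
after four pair joins.

**Terminal cases.** The loop ends when 3 or fewer OTUs remain, or when one
tie group covers everything. Three OTUs form the final star via the
three-point formula; two OTUs (possible when simultaneous joins drop
$4 \to 2$) are connected by a single edge, serialized as a degree-2 root
carrying half the distance on each side. An input of 2 taxa follows the
same single-edge rule.

**A structural tie at $N = 4$.** For any matrix with four active OTUs,
$S_{12} = S_{34} = -(D_{13}+D_{14}+D_{23}+D_{24})$: a pair and its
complement always tie exactly. MFNJ consequently finishes a 4-OTU
endgame by joining both pairs at once ($4 \to 2 \to 1$) whereas classic NJ
joins one pair and ends in a 3-star. The two finishes describe the *same*
unrooted tree — identical splits and identical unrooted edge lengths —
they only root it differently, which is why all topology and length
comparisons in this package go through the unrooted view
(`tree_splits()`, `unrooted_edge_lengths()`), never through the rooted
shape. One real consequence: "no ties at any iteration" is unattainable
for any 4-OTU stage, and a claim that the MFNJ split set equals the
intersection of all classic-NJ outcomes can fail, because one NJ
tie-break branch may lose a split that MFNJ (which never reaches the
degenerate $N=4$ stage on that data) retains. The bundled bear matrix is
exactly such a case: the MFNJ tree's split set is the intersection of the
two NJ trees' split sets *plus* the split separating Abruzzo and Pyrenees
from the rest.

**Classic-NJ tie policy.** `run_nj()` keeps the tied pair that comes
first by (smaller index, larger index) in the current matrix order. This
is deterministic but input-order-sensitive *by design* — it is the
phenomenon being studied. `enumerate_nj()` explores every tied choice
depth-first, deduplicates by unrooted split set, and reports whether the
`enum_cap` truncated the search.

**Numerical robustness.** $R_i$ and $S$ are recomputed from the active
matrix every iteration (no incremental updates); the $O(N^3)$ total cost
is irrelevant at the few-thousand-taxon scale this package targets. Every
updated distance is computed once and mirrored, so the active matrix stays
exactly symmetric with a zero diagonal.

## What the synthetic generator emulates

`random_tree()` builds coalescent-style labeled trees: `n_leaves`
lineages merge (2 at a time, or 3+ with probability `polytomy_prob`) until
one remains, each merged lineage drawing a branch length from
`length_dist` (default uniform on $[0.5, 5]$, a generic continuous choice
that makes selection-criterion ties measure-zero). Polytomies are created
at construction, not by collapsing short edges, so polytomy ground truth
is exact. `additive_matrix()` turns a tree into its path-length metric, on
which neighbor joining is provably consistent; `star_matrix()` builds
$D_{ij} = l_i + l_j$, the fully tied case that MFNJ must collapse into one
polytomy in one iteration with $L_i = l_i$; `perturb()` adds one Gaussian
draw per unordered pair to break ties.

What the generator does **not** emulate: estimation noise with
distance-dependent variance, non-additivity from model misspecification,
missing data, or correlated errors. A green consistency test therefore
establishes correctness of the *algorithm* on its stated input class
(exact additive and star metrics, plus generic random matrices), not
robustness of NJ-family methods on real sequence-derived distances.

## Known limitations

* Tie detection is tolerance-based; inputs engineered with $S$ gaps near
  `tie_rtol` can flip between one polytomy and two iterations.
* `enumerate_nj()` is exponential in the number of tied choices; heavily
  tied matrices (equal-length stars) truncate at `enum_cap`.
* Bootstrap support, phylogenetic networks, and variance-weighted NJ
  variants (BIONJ, weighbor) are out of scope.
* Distances are consumed as given; no estimation from sequences.
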