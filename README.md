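# mfnj — multifurcating neighbor joining

Distance-based phylogenetic tree reconstruction for people who have been
bitten by the **ties-in-proximity** problem: classic neighbor joining (NJ)
can output different trees for the same distance matrix depending only on
the order of the taxa in the input file, because whenever several pairs of
OTUs tie for the minimal selection criterion it must arbitrarily pick one.
`mfnj` implements the multifurcating generalization (MFNJ), which joins
the whole tied group at once into a polytomy, so the result is unique and
input-order invariant — and identical to classic NJ whenever there are no
ties.

## The method in brief

Each iteration over the current $N \times N$ matrix $D$ computes
row sums $R_i = \sum_k D_{ik}$ and the Studier–Keppler criterion

$$S_{ij} = (N-2)\,D_{ij} - R_i - R_j .$$

All pairs within tolerance of $\min S_{ij}$ are collected; their connected
components form the join sets. A join set $I$ becomes a new node $u$ with

$$D_{uk} = \frac{R_{Ik}}{|I|} - \frac{R_{II}}{|I|(|I|-1)}, \qquad
L_{iu} = \frac{R_{II}}{|I|(|I|-1)} + \frac{R_{iI^\complement}}{N-|I|}
       - \frac{R_{II^\complement}}{|I|(N-|I|)},$$

with companion formulas for node–node distances when disjoint sets join in
the same iteration and for the final join (empty complement). For
$|I| = 2$ everything reduces exactly to classic NJ. See the vignette in
`vignettes/multifurcating-neighbor-joining.Rmd` for the full model,
tolerances, and design notes.

## Worked example: nine brown bears

The package ships the classic demonstration matrix of pairwise percentage
differences among mitochondrial DNA sequences of nine brown bears
(`bear_matrix()`, also in `inst/extdata/bears.phy`). Classic NJ admits two
distinct trees on it; MFNJ returns one.

```r
library(mfnj)
res <- run_mfnj(bear_matrix())
to_newick(res$tree)
```

```
(Abruzzo:0.833333,Pyrenees:0.466667,(Captive-4:1.75,Black:7.6,
 ((Captive-5:0.1,(Kodiak:0.35,Captive-3:0.35):0.85):1.3,
  (Grizzly:-0.02,Polar-2:0.32):0.4):0.75):0.1);
```

(one line in the real output; wrapped here). Reading the join log: the
first four iterations pair up Kodiak+Captive-3, then Captive-5, then
Grizzly+Polar-2, building the five-bear subtree. At iteration 5 two pairs
tie for the minimal $S$ — (Captive-4, subtree) and (subtree, Black) — so
MFNJ joins **Captive-4, the subtree, and Black into one trifurcation**,
visible as the internal node with three children above. The `-0.02` is a
negative branch length, kept faithfully by default
(`mfnj_config(negative_branch = "clamp_to_zero")` clamps for display).

Classic NJ instead must break the tie, and both resolutions exist:

```r
en <- enumerate_nj(bear_matrix())
length(en$trees)   # 2 distinct unrooted topologies
```

Input-order invariance can be audited directly:

```r
res$tree |> tree_splits()     # 5 splits: 9 leaves, one polytomy
```

permuting the taxon order 100 times yields the same split set and the
same unrooted edge lengths every time (`test-acceptance.R`, criterion 9).

## Command line

An `Rscript` front end lives at `system.file("scripts", "mfnj", package =
"mfnj")`:

```sh
mfnj mfnj bears.phy                       # Newick with a polytomy
mfnj nj bears.phy --log joins.jsonl       # classic NJ + join log
mfnj enumerate bears.phy                  # all tie-break outcomes
mfnj simulate --n-leaves 20 --seed 1 -o sim.phy --tree-out truth.nwk
mfnj audit bears.phy --permutations 100 --seed 1
```

`audit` prints `permutations=100 distinct_results=1 agree=true`. Exit
status: 0 success, 2 malformed input, 1 internal error. PHYLIP (square or
lower-triangular), CSV and TSV matrices are accepted; format is inferred
from the extension or forced with `--format`.

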