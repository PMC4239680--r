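# gordalign

Ancestral gene-order reconstruction on a species tree under a
duplication–loss–reversal model of genome evolution.

## What problem does this solve?

For closely related genomes — bacterial strains, organelles, stable-RNA
gene repertoires — most differences are not point mutations but changes
in gene **order and copy number**: segmental duplications, losses and
inversions.  Given the gene orders of extant genomes (strings of signed
gene-family symbols, paralogs allowed) and a rooted binary species tree,
`gordalign` infers a gene order for **every ancestral node** and an
explicit, replayable event scenario for every branch, minimising the
total event cost on the tree.  It is aimed at comparative genomicists
studying gene-cluster evolution at short evolutionary distances, where
events are still *visible*: each gene participates in at most one event.

## The method in brief

The objective is the phylogenetic alignment cost
`sum over branches (u -> v) of C(u -> v)`, where `C(u -> v)` is the
minimum summed cost of events `D(k)` (duplication), `L(k)` (loss) and
`R(k)` (reversal) transforming the parent assignment into the child's.
Because duplications and losses are not symmetric under time reversal,
direction matters, and the local subproblem is the **directed 3-star**:
for a node `M` with grandparent assignment `A` and children `X`, `Y`,
find the center `M` and histories minimising
`C(A -> M) + C(M -> X) + C(M -> Y)`.

The 3-star is solved heuristically by dynamic programming over a table
`C(i, j, k)` of labeled-alignment costs of the prefixes `A[1..i]`,
`X[1..j]`, `Y[1..k]`, interpreting the final column block as a match, a
reversal, a duplication or a loss attributed to one of the three
branches (at most two same-length events per block).  The backtracked
labeling may contain circular chains of mutually-sourcing duplications;
a repair step re-reads one chain member as a block present in the
center — a loss in the sibling plus the fewest ancestor-sourced
duplications covering it — until the labeling is feasible, i.e.
corresponds one-to-one to a valid event history.  A steinerization loop
(initialise parents from sibling alignments bottom-up, then re-solve the
3-star at each internal node until no improvement) drives the whole-tree
reconstruction; the total cost is non-increasing by construction.

The package also ships a ground-truthed simulator of gene-order
evolution and an exhaustive branch-and-bound oracle that certifies exact
optima on small instances — the reference used throughout the test
suite.  See the methods vignette
(`vignettes/gene-order-phylogeny.Rmd`) for the model, the full case
vocabulary, tie-breaking rules and design caveats.

## Worked example

The three genomes `A = abcde` (the grandparent), `X = acdeabdeabde` and
`Y = acde`:

```r
library(gordalign)
sp <- function(s) strsplit(s, "")[[1]]
sol <- solve_star(star_instance(sp("abcde"), sp("acdeabdeabde"), sp("acde")))
print(sol)
#> 3-star solution: cost 5
#>  center: a c d e a b d e
#>  branch costs: A>M=3  M>X=1  M>Y=1
print(sol$alignment)
#> labeled alignment (star), 13 columns, 5 events
#>  A        a b c - - - - - - - - d e
#>  X        a - c d e a b d e a b d e
#>  Y        a - c - - - - - - - - d e
#>  (center) a - c d e a b - - - - d e
```

Reading: the center `M = acdeabde` lost gene `b` relative to `A` and
gained `de` + `ab` by two duplications sourced in `A` (3 events on
`A -> M`); `X` then duplicated the `abde` block once more (1 event), and
`Y` lost it (1 event) — 5 events in total.  The raw dynamic program
first proposes a cheaper (3-event) labeling in which the two `abde`
copies in `X` each claim the other as duplication source; that circular
labeling corresponds to no real history, and the repair step converts
it into the feasible 5-event scenario above.  `sol$histories` holds the
three branch histories; replaying them reproduces `M`, `X` and `Y`
exactly.

On a tree, with simulated genomes:

```r
set.seed(7)
sim <- simulate_tree(6, sim_params(n = 20, sigma = 10, l = 2))
tr  <- run_steinerization(sim$phy, sim$genomes,
                          costs = dup_singleloss_costs())
tr$rounds
#>   round cost n_improved
#> 1     0   24         NA
#> 2     1   22          1
#> 3     2   22          0
```

Initialization explains the six leaves with 24 duplication /
single-gene-loss events; one reoptimization round improves an internal
node, reaching a local minimum of 22 (the simulation used 20 true
events; at this event density slight over-counting is expected).
`write_results(tr, dir)` emits the assignments, per-round costs and the
annotated newick tree.

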