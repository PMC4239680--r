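---
title: "Ancestral gene orders on a phylogeny: model, algorithms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral gene orders on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gordalign)
```

## The problem and the model

Closely related genomes — bacterial strains, organellar genomes, tRNA/rRNA
gene repertoires — often differ not by point mutations but by the order
and copy number of their genes.  `gordalign` treats a genome as a *gene
order*: a string of signed gene-family symbols in which the same family
may appear several times (paralogs) and the sign is the transcriptional
orientation.  Evolution acts through three operations, each with a
*source* (the block it reads) and a *target* (the block it writes):

* **duplication** `D(k)`: a copy of a k-gene block is inserted outside
  its source interval;
* **loss** `L(k)`: a contiguous k-gene block is deleted;
* **reversal** `R(k)`: a block is replaced by its reverse (order flipped,
  signs flipped).

A duplication whose source lies in a *different* genome than its target
doubles as a transposition or a lateral transfer followed by loss of the
source copy; the package takes this general view, so transpositions are
never modelled separately.  A `cost_scheme` prices each operation as a
function of its length.  The default charges 1 per event;
`dup_singleloss_costs()` encodes the classical duplication /
single-gene-loss comparison model (a k-gene loss counts as k events,
reversals disabled).

For genomes this close, we assume events do not overlap: every gene takes
part in at most one event, so all events are still *visible* in an
alignment of the genomes.  This is the regime in which the method is
meaningful; deeply diverged genomes violate it and the inferred counts
become lower bounds of decreasing usefulness.

## Labeled alignments

A *labeled alignment* is a gap-padded alignment together with a set of
events explaining every non-match column: matches are covered by no
event, a mismatched column pair by exactly one reversal, a gap pair by
exactly one duplication (the character side is the new copy) or loss (the
character side is the ancestral block).  When one row is ancestral, every
event points down the tree.  `validate_alignment()` checks these clauses
pair by pair, restricting attention to events on the path between the two
rows.

A labeling is only a genuine event scenario when it is *feasible*: no
circular chain of operations in which each operation's target overlaps
the next operation's source (each needs part of the other's output to
exist first).  Events sourced in the ancestral row cannot participate in
such chains, and in labelings produced by the dynamic program every
chain member is provably a duplication; `find_cycles()` asserts this at
run time.

## The directed 3-star problem

The core engine answers: given a grandparent assignment `A` and two
siblings `X`, `Y`, which center genome `M` minimises the summed event
cost of the three branches `A→M`, `M→X`, `M→Y`?  Direction matters —
a duplication seen from below is a loss seen from above — so this is a
*directed* median, not a symmetric one.

`compute_dp()` fills a table `C(i, j, k)` over prefix triples with the
minimum cost of a labeled alignment of `A[1..i]`, `X[1..j]`, `Y[1..k]`,
interpreting the last column block as one of fourteen cases: the all
match column; reversals in the center, in one child, or in the center
with a loss in one child; duplications shared by both children (source
occurring in `A`), in one child alone (source occurring in `A`, in the
other child, or disjointly elsewhere in the same child), or combined
with a reversal in the sibling; and losses in one child, both children,
or the center.  Compound cases charge two events of the same block
length; a column with three distinct characters is inadmissible (it
would need two reversals of different lengths).  Block lengths range
over every admissible extension, found by scanning suffixes backwards.
The search is a heuristic: operations whose column sets interleave
(e.g. a duplication whose copy later lost an interior gene) are outside
its vocabulary, which is precisely where it can over-count relative to
the exact optimum.

Equal-cost interpretations are broken by a fixed priority — match,
losses, shared duplication, reversals, solo duplication, compound cases,
preferring longer blocks within a case — chosen to keep the center close
to the ancestor and make backtracking deterministic.
`evaluate_cases()` re-derives every cell candidate in plain R and is
tested cell-by-cell against the compiled table.

`backtrack_alignment()` reconstructs the three-row alignment, the
column-aligned center and the event set.  Duplication sources are
resolved preferring the ancestor (which can never create a cycle), then
a disjoint occurrence in the same child, then the other child.

## Cycle resolution

The backtracked labeling may contain duplication cycles (mutually
sourcing copies).  `resolve_cycles()` repairs them one at a time: among
the cycle members it picks the block `Z` whose minimum decomposition
into ancestor-occurring parts (`min_decomposition()`, a shortest-path
over cut positions) has the fewest parts, re-reads `Z` as having been
present in the center — hence a loss in the sibling — and charges one
duplication from the ancestor per part.  Each repair removes one
child-internal duplication, so the loop terminates, and the output is
certified cycle-free.  In the pairwise sibling case the repair is
simpler: the block moves into the parent and becomes a loss in the
sibling.  When no cycle member decomposes over the ancestor (possible
only for inputs that did not evolve from the given ancestor), a
per-gene fallback sources each gene wherever it occurs; in directed
mode an unplaceable gene is an error unless `allow_gain = TRUE`
explicitly prices it as a gain from an unobserved lineage.

`extract_center()` then reads off `M` and orders each branch's events
into a replayable history (losses right-to-left, then reversals, then
duplications left-to-right, in the coordinates of the genome they apply
to).  Every history is replayed at construction and must reproduce its
endpoint exactly; this is asserted, not assumed.

## Pairwise alignment and the tree loop

`align_siblings()` and `align_directed()` are two-row restrictions of
the same case vocabulary (implemented by their own compiled kernels) and
feed the tree phase: `initialize_assignments()` walks the tree bottom-up
assigning each internal node the parent implied by its children's
sibling alignment; `reoptimize_round()` then revisits every internal
node, solves the 3-star formed by its parent and children, and adopts
the new center only when the three recomputed directed branch costs
strictly improve — so the total tree cost is non-increasing and the loop
(`run_steinerization()`) terminates, by default within 20 rounds
(observed instances converge in far fewer).  Nodes are updated in place
during a sweep, children before parents; a snapshot sweep was the
alternative, but accepting against current neighbours is what guarantees
the monotonicity invariant.  The root has no grandparent, so it is
re-estimated from the sibling alignment of its two children; its
children use the root as their 3-star ancestor.  Replacement candidates
are always re-priced with `align_directed(..., allow_gain = TRUE)`: a
center proposing content that a branch cannot source is thereby priced
honestly rather than rejected on a technicality, and candidates that do
not improve are discarded.

`build_multiple_alignment()` merges the directed parent–child alignments
bottom-up into one gap-consistent matrix over all nodes, the usual
reference-row merge of progressive alignment.

## The simulator

`simulate_tree()` / `simulate_star()` generate ground-truthed instances:
a uniform random root of `n` genes over `sigma` families receives `l`
moves, and every other genome receives `l` moves from its direct
ancestor.  Under `"dup_singleloss"` a move is, with equal probability, a
duplication — length geometric with parameter 0.5 (mean 2), source start
uniform, insertion point uniform outside the source — or the loss of one
uniformly chosen gene; `"dup_loss_reversal"` adds reversals with the
same length law.  The 50/50 (or equal-thirds) kind mixture and the
uniform position laws are package choices where no standard exists; a
loss that would empty a genome is resampled.  Every branch history is
retained and replays exactly.

The simulator emulates copy-number and order evolution only: no gene
births, no sequence-level divergence, no rate heterogeneity across
branches, and exactly `l` events per branch rather than a stochastic
count.  Passing tests therefore certify algorithmic behaviour under the
stated model, not performance on annotations extracted from real
genomes, where family assignment errors and model violations add noise
the tests do not probe.

## The exact oracle

`exact_pair_cost()` and `exact_star_cost()` provide the reference
optimum for small instances.  They search the space of event
*histories* — sequences of duplications, losses and optionally
reversals applied to the intermediate genome at unit cost per event —
by iterative deepening over the total count, splitting the 3-star budget
over the three branches (splits with a zero component collapse to plain
reachability queries; only all-positive splits enumerate candidate
centers).  Pruning uses admissible bounds: family counts (a missing
family is unreachable; surplus copies need losses; a shortfall needs a
duplication), new adjacency types (each duplication or loss introduces
at most two adjacency types absent from the current genome; invalid for
reversals and therefore skipped in that model), and length doubling.
Within its budget the search is exact for this sequential formulation
by exhaustion.

Two design caveats are deliberate.  First, the labeling model prices a
cross-lineage duplication (the transposition surrogate) as one event,
while any sequential history needs a duplication plus a loss for the
same effect; the heuristic can therefore — rarely — return a *lower*
cost than the oracle, and the test suite asserts that every such case
involves a third-genome-sourced duplication.  Second, in the sibling
(unknown-parent) mode the inverse-loss candidates are restricted to
single genes of the observed families and blocks observed in a leaf; a
minimal parent needs no other content in the regimes tested, but this
mode is exercised only on tiny instances.  The star and directed modes,
which the validation experiments rely on, search forward only and carry
no such restriction.

The oracle accepts the best known achievable cost as an upper cap
(`upper`): it still exhausts every smaller total, so the returned
optimum is unchanged — the cap only skips re-deriving a witness whose
cost is already certified by a replayed heuristic history.  The suite
checks capped and free searches agree.

## Numerical and representational choices

* Intervals are 1-based inclusive at the R surface and converted once
  for the compiled kernels; alignment columns are indexed from 1.
* Infeasible table cells carry IEEE `+Inf` in a double-precision table —
  well-defined in both R and C++ and safe under addition — rather than a
  finite sentinel.
* Cost ties are resolved by the fixed priority order described above;
  cycle repair processes the smallest cycle first and prefers blocks in
  the first child, then leftmost columns.  All outputs are deterministic
  functions of their inputs.
* Degenerate inputs: empty genomes align at cost 0; an instance whose
  child contains a gene family occurring nowhere else is correctly
  reported as inadmissible rather than silently patched (see
  `allow_gain`).
* Unsigned data are handled by `signed = FALSE`, under which a reversal
  only reverses the reading order; with all-positive signed tokens a
  reversal can never match, which is the conservative default.

## Validation scale

The packaged experiments run at desk scale on one core: 50 replicate
3-star instances with `n = 20`, `sigma = 10`, `l = 1` (the ratios
`sigma/n = 1/2`, `l/n = 1/20`), an `l/n` grid realised by shrinking `n`
at one move per branch, twenty 6-leaf steinerization runs at `n = 16`,
`l = 2`, and property suites on instances of up to ~12 genes.  At these
sizes the exact oracle is exhaustive within seconds.  The accuracy
statistic is the fraction of replicates where the heuristic's event
count equals the oracle optimum, and the error statistic is the mean of
`(inferred - optimal)/inferred`; note that at 50 replicates each miss
moves the mean error by roughly 0.005, so that statistic is grainy at
this scale.

## Limitations

* Single-chromosome gene orders only; no translocations or fusions.
* The 3-star solver and the tree loop are heuristics: steinerization
  converges to a local minimum that depends on the initialization, and
  the median itself carries no optimality guarantee.
* The model assumes visible, non-overlapping events; as event density
  grows (`l/n` well above ~1/10) the inferred counts increasingly
  exceed the true ones.
* Tree topology is taken as given; no topology search, no branch
  lengths.
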