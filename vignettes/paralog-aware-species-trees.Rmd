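---
title: "Paralog-aware species-tree estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paralog-aware species-tree estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discoq)
```

## The problem

Summary methods infer a species tree from a collection of gene trees.  Two
biological processes make gene trees disagree with the species tree and with
each other: incomplete lineage sorting (ILS), in which ancestral polymorphism
persists across speciations, and gene duplication and loss (GDL), which
creates paralogs so that a single gene family tree may carry several leaves
per species (a multi-labeled, or MUL, tree).  Quartet-based methods such as
the maximum-quartet-consistency family handle ILS well but require
single-copy trees.  `discoq` bridges the gap: it tags and decomposes
multi-copy trees into single-copy trees and then amalgamates their quartets,
so that GDL-affected gene families can feed a quartet amalgamation that is
consistent under the joint duplication-loss-coalescence (DLCoal) model.

The pipeline is

1. **Root and tag** (`root_and_tag()`): every internal node of a rooted gene
   tree is a *duplication* if its two child subtrees share at least one
   species, a *speciation* otherwise.  Unrooted input is rooted on the edge
   whose tagging minimizes a weighted duplication-loss parsimony score.
2. **Decompose** (`decompose()`): at every duplication node (postorder) one
   child subtree is pruned and emitted; the `disco-r` mode additionally
   regrafts, at the duplication point, a copy of the pruned subtree trimmed
   to the species absent from the remaining backbone.  Each input tree with
   D duplication nodes yields D + 1 single-copy trees.
3. **Weight quartets** (`gtf_table()`): for every output tree, every 4-subset
   of its species contributes one unit of weight to its induced quartet
   topology (gene-tree-frequency weighting).
4. **Amalgamate** (`exact_wmqc()` / `heuristic_wmqc()`): find the unrooted
   binary species tree maximizing the total weight of consistent quartets
   (weighted maximum quartet consistency, WMQC).

## Rooting and tagging

Tagging is purely topological and idempotent.  The parsimony score of a
tagged rooted tree is `w_dup * D + w_loss * L`: `D` counts duplication
nodes, and the implied losses at a duplication with child species sets `A`
and `B` are `|A \ B| + |B \ A|` -- a species seen under one duplicate but
not the other must have lost a copy.  Speciation nodes contribute nothing.
The published tagging heuristic this mirrors leaves its loss count in
supplementary material, so the formula above is this package's own
definition; it is species-tree-free, monotone in the asymmetry of the two
duplicate subtrees, and isolated in one function so it can be swapped.  The
defaults `w_dup = w_loss = 1` weight both event types equally.

Rooting scores all `2n - 3` edges and keeps the first minimizer in a
deterministic postorder edge enumeration started at the leaf with the
lexicographically smallest label, so reruns are reproducible.  Scoring is
recomputed per candidate root (quadratic overall), which is transparent and
plenty fast at the tree sizes the decomposition stage sees.

## Decomposition and its variants

`prune_strategy` selects which child of a duplication node is pruned:
`"larger"` (default) prunes the strictly larger child and, on ties, the
right child; `"smaller"` mirrors it (ties again to the right); `"random"`
draws a side per duplication from a user seed.  Published descriptions of
the decomposition differ on larger-versus-smaller; the default here follows
the pseudocode form with a strict "larger than" comparison, and the variant
switch exposes the alternatives.

Two choices in `disco-r` were genuinely open:

* **Copy semantics.**  The emitted tree at a duplication is the *untrimmed*
  pruned subtree; trimming and regrafting operate on a separate copy.
  Anything else would mutate an already-emitted output.
* **Size comparisons** at a duplication use the *current* subtree sizes,
  i.e. after any regrafts performed deeper in the tree, which is the literal
  reading of a single postorder pass over the evolving tree.

Degenerate regrafts are handled explicitly: if trimming removes every leaf
of the copy, nothing is attached and the degree-2 node is contracted; a
single surviving leaf is attached directly.  Outputs with fewer than four
leaves are kept in the result (the backbone always carries all species in
`disco-r`) but induce no quartets downstream.

## Speciation-driven quartets

A quartet of four genes from four distinct species is *speciation-driven*
(SQ) when every cross-pair LCA of its induced pairing is a speciation node.
The defining phrase in the literature ("the LCA of either a or b with
either c or d") is ambiguous between "some" and "all"; the worked
single-duplication example used throughout the test suite is only
reproduced under the "all cross-pair LCAs" reading, which is therefore the
one implemented.  `sq_set()` reports SQs at species level after requiring
the four genes to come from distinct species.  The plain decomposition's
outputs cover only SQs but not all of them; regrafting recovers more SQs at
the price of some non-SQ quartets -- both behaviors are pinned by tests on
the worked example and on random simulated families.

## Weighted maximum quartet consistency

GTF weights are raw integer counts; any normalization is left to consumers.
`exact_wmqc()` enumerates all `(2n-5)!!` unrooted binary topologies by
deterministic stepwise addition (guarded to `n <= 9`), scores each against
the table through a cached topology-by-quartet index matrix, and returns the
first maximizer.  It is the correctness anchor: tests compare it against an
independent exhaustive scan built on a different tree enumeration.

`heuristic_wmqc()` follows the quartet-Fiduccia-Mattheyses discipline: the
taxon set is split by a seed-driven random balanced bipartition, improved by
single-taxon moves chosen by quartet-weight gain (satisfied minus violated
weight of quartets with a 2-2 straddle), each taxon locked after moving and
the best prefix of the move sequence kept; passes repeat until no
improvement.  Quartets with a 3-1 straddle are deferred into the subproblem
by a dummy taxon standing for the far side; 4-taxon subproblems are solved
exactly over the three pairings.  Both sides of a split are kept at size at
least two so the recursion strictly shrinks.  Because a single random
initial split occasionally commits to a poor basin, the solver takes five
seeded restarts and keeps the best-scoring tree; everything is deterministic
given the seed.  The published amalgamation heuristic's internals (its
initial bipartition and gain definitions) are not restated in the source
literature, so the details above are this package's own, validated against
the exact solver (better than 90% topology agreement on low-noise
eight-taxon instances in the acceptance suite) and bounded by it whenever
the exact solver applies.

## The DLCoal simulator

`generate_dataset()` draws gene families under the two-stage DLCoal model:

* **Top-down duplication/loss.**  Along every lineage of the species tree,
  duplications (rate λ+ per gene per generation) and losses (λ−) arrive as
  independent Poisson processes; a duplication spawns a daughter locus that
  continues down the species tree, a loss terminates the lineage.  Lost
  lineages are pruned; fully extinct families are reported as extinct and,
  in dataset generation, redrawn (conditioning on survival) with the redraw
  count recorded.
* **Bottom-up bounded coalescence.**  Within each locus-tree branch the
  standard coalescent with haploid population size N runs bottom-up; at a
  duplication the daughter locus must reduce to a single ancestral lineage
  by the duplication time.  The bound is enforced by rejection -- the
  daughter subtree's coalescent history is redrawn until the constraint
  holds, with a retry cap -- which is exact where it terminates and avoids
  bounded-coalescent densities.  The cap can be genuinely unreachable when a
  duplication falls immediately above a speciation (the daughter branch is
  then too short for its forced-to-enter lineages to coalesce), so
  `simulate_gene_tree()` raises a classed error on exhaustion and
  `generate_dataset()` redraws such a family the way it redraws extinct
  ones, reporting the count (`n_bound_redraws`).  This discards a small,
  reported fraction of families with near-node duplications; at the rates
  used here the fraction is on the order of 10^-3 or less.

Branch lengths are in generations and one coalescent unit is N generations,
so test scenarios use N = 1 and coalescent-unit branch lengths directly;
published per-year rates can be mapped in by the user's years-per-generation
conversion.  The simulator emulates topology-generating processes only: it
does not model sequence evolution or gene-tree estimation error, so passing
tests demonstrate behavior on *true* gene trees, not robustness to
reconstruction noise.  Mother/daughter identity is recorded at every
duplication so tests can confirm that pruned subtrees track novel loci.

## Study conditions used by the test suite

The statistical checks run at deliberately desk-scale sizes, chosen once as
conditions a simulation study would call moderate:

* Quartet-frequency behavior (a four-taxon tree with λ+ = λ− = 0.05 per
  coalescent unit, 10 000 families): the species-topology quartet is
  strictly most frequent and the two minority topologies are symmetric
  within a 95% confidence interval.
* The coalescent closed form (no GDL, internal branch T = 1): observed
  discordance within three standard errors of `1 - (2/3) exp(-T)` at 3000
  families.
* Consistency of the full pipeline: a six-taxon species tree with
  0.3-coalescent-unit internal branches (substantial ILS) and
  λ+ = λ− = 0.1, replicated 20 times at gene counts 10/50/200/1000;
  recovery of the true species tree must be non-decreasing in gene count
  and reach 1.0 at 1000 genes.  The shorter internal branches make the
  small-gene-count regime genuinely hard, so the curve is informative
  rather than saturated.

## Numerical and degenerate-input choices

* Quartet topologies are keyed canonically (`"a,b|c,d"`, labels sorted
  within pairs, pairs ordered by smallest member); induced topologies are
  computed from unit-edge path lengths via the four-point condition, which
  is tie-free on binary trees.
* Scores are plain sums; GTF weights are integers, so integer arithmetic is
  exact within double precision.
* Polytomies are accepted at parse and resolved deterministically
  (left-to-right caterpillar) before tagging, which requires binary nodes.
* Single-leaf and two-leaf trees pass through rooting untouched; trees with
  fewer than four leaves contribute no quartets.
* Mismatched leaf sets in tree comparison are an error, never a silent
  restriction; the normalization denominator `2(n-3)` presumes binary
  trees, and polytomous estimates are refused.

## Limitations

* The exact solver is factorially bounded (n ≤ 9); larger taxon sets rely
  on the heuristic, whose quality is only empirically characterized.
* The duplication-loss parsimony loss count is this package's definition
  (see above); other taggers may differ on asymmetric duplications.
* The rejection sampler for the daughter-lineage bound can be slow when
  many lineages enter a short daughter branch; it fails loudly at the retry
  cap rather than silently biasing the draw.
* Quartet enumeration is exhaustive (quartic); that is the intended scale
  for decomposition outputs, not an all-purpose quartet counter.
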