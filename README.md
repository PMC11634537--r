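# discoq

Species-tree estimation from **multi-copy gene family trees** — gene trees in
which duplication and loss (GDL) have left several gene copies per species —
under simultaneous incomplete lineage sorting (ILS).  `discoq` is aimed at
phylogenomics practitioners who have a collection of (possibly multi-labeled)
gene trees and want a species tree without first calling orthology.

## What it computes

Most quartet-based summary methods are statistically consistent under the
multispecies coalescent but require single-copy gene trees.  `discoq`
implements the decomposition route to paralog awareness:

1. **Duplication/speciation tagging and parsimony rooting.**  An internal
   node of a rooted gene tree is a *duplication* iff its two child subtrees
   share a species.  Unrooted trees are rooted on the edge minimizing
   `w_dup·D + w_loss·L`, where `D` is the duplication count and the losses at
   a duplication with child species sets `A`, `B` are `|A\B| + |B\A|`.
2. **Decomposition.**  At every duplication node (postorder) one child
   subtree is pruned and emitted, yielding `D + 1` single-copy trees per
   input.  The *regrafting* variant (`disco-r`) additionally reattaches, at
   the duplication point, a copy of the pruned subtree restricted to the
   species missing from the backbone, so no species is ever lost and more
   speciation-driven quartets survive.
3. **Quartet weighting.**  Every 4-subset of species of every single-copy
   tree contributes a unit of gene-tree-frequency (GTF) weight to its
   induced topology `ab|cd`.
4. **Weighted maximum quartet consistency (WMQC).**  Find the unrooted
   binary tree `T` maximizing `Σ_q w(q)·[q consistent with T]` — exactly by
   topology enumeration for ≤ 9 taxa, or by a Fiduccia–Mattheyses-style
   divide-and-conquer heuristic for larger sets.

A DLCoal simulator (top-down duplication/loss producing a locus tree,
bottom-up bounded coalescent producing the gene tree) generates test data,
and Robinson–Foulds utilities evaluate estimates.

## Worked example

The package's running example is a gene family over nine species in which
species `c` and `d` are present twice:

```r
library(discoq)
fig1 <- "(((a_1,b_1),p_1),(((c_1,d_1),(f_1,g_1)),((c_2,h_1),(d_2,e_1))));"
res <- run_pipeline(fig1, method = "exact")
print(res)
#> pipeline_result (disco-r, exact WMQC): 1 gene trees -> 9 species
#>   duplication nodes: 1; single-copy trees: 2; quartet topologies: 127 (weight 127)
#>   normalized quartet score: 0.9921
#>   species tree: (b,((((c,d),(f,g)),(e,h)),p),a);
```

One node is tagged as a duplication (its children both contain `c` and `d`),
so the decomposition yields two single-copy trees: the pruned subtree
`((c,h),(d,e))` and the regrafted backbone
`(((a,b),p),(((c,d),(f,g)),(h,e)))`.  Their pooled 127 quartets conflict on
exactly one 4-set (`{c,d,e,h}` is resolved differently by the two trees), so
the best possible tree satisfies 126 of 127 — the reported score
`0.9921 = 126/127`.  The estimate keeps the backbone's groupings
(`(c,d)` with `(f,g)`, `e` with `h`, `(a,b)` with `p`).

Individual stages are available directly:

```r
t   <- resolve_species(parse_newick(fig1), delimiter_mapping("_"))
tt  <- tag_rooted(t)                   # or root_and_tag() for unrooted input
dec <- decompose(tt, mode = "disco-r") # mode = "disco" for plain pruning
tab <- gtf_table(dec)
exact_wmqc(tab, sort(unique(tree_species(t))))
```

and `generate_dataset(dlcoal_params(...))` simulates multi-copy families for
benchmarking (see the methods vignette for the model and its knobs).

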