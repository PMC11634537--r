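# Independent oracles and fixture builders used across the suite.
# Oracles deliberately take different code paths from the package
# implementation: ape/phangorn/phytools machinery plus brute-force recounts.

fig1_newick <- "(((a_1,b_1),p_1),(((c_1,d_1),(f_1,g_1)),((c_2,h_1),(d_2,e_1))));"

fig1_tagged <- function() {
  tag_rooted(resolve_species(parse_newick(fig1_newick), delimiter_mapping("_")))
}

# random single-copy species-labelled tree via ape
rand_tree <- function(n, labels = paste0("s", seq_len(n))) {
  ph <- ape::rtree(n, tip.label = sample(labels))
  resolve_species(parse_newick(ape::write.tree(ph)), identity_mapping())
}

# ---- bipartition-set RF oracle ------------------------------------------

# nontrivial splits of a phylo as canonical "side|side" strings
oracle_splits <- function(ph) {
  ph <- ape::unroot(ph)
  tips <- sort(ph$tip.label)
  n <- length(tips)
  internal <- which(ph$edge[, 2] > n)
  out <- character(0)
  for (e in internal) {
    below <- ape::extract.clade(ph, ph$edge[e, 2])$tip.label
    side <- sort(below)
    if (length(side) < 2 || length(side) > n - 2) next
    other <- sort(setdiff(tips, side))
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(paste(side, collapse = ","), paste(other, collapse = ","), sep = "|")
    else
      paste(paste(other, collapse = ","), paste(side, collapse = ","), sep = "|")
    out <- c(out, key)
  }
  unique(out)
}

oracle_rf <- function(t1, t2) {
  p1 <- if (inherits(t1, "phylo")) t1 else discoq:::as_species_phylo(t1)
  p2 <- if (inherits(t2, "phylo")) t2 else discoq:::as_species_phylo(t2)
  s1 <- oracle_splits(p1); s2 <- oracle_splits(p2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# ---- brute-force quartet oracles ----------------------------------------

# induced quartet of 4 species via ape::keep.tip and split comparison
oracle_quartet <- function(tree, sp4) {
  ph <- discoq:::as_species_phylo(tree)
  sub <- ape::unroot(ape::keep.tip(ph, sp4))
  split <- oracle_splits(sub)
  stopifnot(length(split) == 1)
  pair1 <- strsplit(strsplit(split, "|", fixed = TRUE)[[1]][1], ",")[[1]]
  pair2 <- setdiff(sp4, pair1)
  discoq:::canonical_quartet(pair1, pair2)
}

# per-tree, per-4-subset recount of the GTF table
oracle_gtf <- function(trees) {
  keys <- character(0)
  for (t in trees) {
    sp <- sort(tree_species(t))
    if (length(sp) < 4) next
    for (q in utils::combn(length(sp), 4, simplify = FALSE))
      keys <- c(keys, oracle_quartet(t, sp[q]))
  }
  tb <- table(keys)
  quartet_table(stats::setNames(as.numeric(tb), names(tb)))
}

# ---- independent duplication-loss scorer --------------------------------

# tags and scores a rooted species-labelled phylo from scratch
oracle_dl_score <- function(ph, species_of, w_dup = 1, w_loss = 1) {
  n <- length(ph$tip.label)
  score <- 0
  for (node in (n + 1):(n + ph$Nnode)) {
    kids <- ph$edge[ph$edge[, 1] == node, 2]
    stopifnot(length(kids) == 2)
    spset <- lapply(kids, function(k) {
      tips <- if (k <= n) ph$tip.label[k] else ape::extract.clade(ph, k)$tip.label
      unique(species_of(tips))
    })
    if (length(intersect(spset[[1]], spset[[2]])) > 0) {
      losses <- length(setdiff(spset[[1]], spset[[2]])) +
                length(setdiff(spset[[2]], spset[[1]]))
      score <- score + w_dup + w_loss * losses
    }
  }
  score
}

# minimum dl score over all rootings, enumerated independently via phytools
oracle_min_rooting_score <- function(tree, w_dup = 1, w_loss = 1) {
  ph <- discoq:::gene_tree_to_phylo(tree, labels = "gene")
  if (is.null(ph$edge.length)) ph <- ape::compute.brlen(ph)
  ph <- ape::unroot(ph)
  species_of <- function(tips) sub("_.*$", "", tips)
  scores <- vapply(seq_len(nrow(ph$edge)), function(e) {
    rooted <- phytools::reroot(ph, ph$edge[e, 2],
                               position = ph$edge.length[e] / 2)
    oracle_dl_score(ape::multi2di(rooted), species_of, w_dup, w_loss)
  }, numeric(1))
  min(scores)
}

# ---- simulation fixtures -------------------------------------------------

# small multi-copy dataset; species names are single letters so the "_"
# delimiter convention applies to gene labels
sim_dataset <- function(n_genes, seed, sp = "((((A:1,B:1):1,C:2):1,D:3):1,(E:3,F:3):1);",
                        dup = 0.08, loss = 0.08, N = 1) {
  generate_dataset(dlcoal_params(parse_newick(sp), dup, loss, N,
                                 n_genes = n_genes, seed = seed))
}

# correctly tagged versions of the true (rooted) simulated gene trees
sim_tagged_trees <- function(ds, min_leaves = 2) {
  trees <- Filter(function(g) n_leaves(g) >= min_leaves, ds$gene_trees)
  lapply(trees, function(g) tag_rooted(resolve_species(g, ds$mapping)))
}
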