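dm <- delimiter_mapping("_")

expect_tree_equal <- function(t1, newick2) {
  t2 <- resolve_species(parse_newick(newick2), identity_mapping())
  expect_equal(rf_distance(t1, t2)$rf_raw, 0)
}

test_that("the worked single-duplication example decomposes as described", {
  fix <- fig1_tagged()

  d <- decompose(fix, mode = "disco")
  expect_equal(length(d$outputs), 2L)
  expect_equal(d$provenance, c("pruned@dup1:R", "backbone"))
  # pruned tree ((c,h),(d,e)); backbone keeps {a,b,p,c,d,f,g}
  expect_setequal(tree_species(d$outputs[[1]]), c("c", "h", "d", "e"))
  expect_tree_equal(d$outputs[[1]], "((c,h),(d,e));")
  expect_setequal(tree_species(d$outputs[[2]]), c("a", "b", "p", "c", "d", "f", "g"))
  expect_tree_equal(d$outputs[[2]], "(((a,b),p),((c,d),(f,g)));")

  dr <- decompose(fix, mode = "disco-r")
  expect_equal(length(dr$outputs), 2L)
  expect_tree_equal(dr$outputs[[1]], "((c,h),(d,e));")
  # the backbone regains (h,e) at the duplication point
  expect_setequal(tree_species(dr$outputs[[2]]),
                  c("a", "b", "p", "c", "d", "f", "g", "h", "e"))
  expect_tree_equal(dr$outputs[[2]], "(((a,b),p),(((c,d),(f,g)),(h,e)));")

  for (o in c(d$outputs, dr$outputs)) expect_true(check_single_labeled(o))
})

test_that("trees without duplications pass through unchanged", {
  t <- tag_rooted(rand_tree(7))
  for (mode in c("disco", "disco-r")) {
    d <- decompose(t, mode = mode)
    expect_equal(length(d$outputs), 1L)
    expect_equal(d$provenance, "backbone")
    expect_equal(rf_distance(d$outputs[[1]], t)$rf_raw, 0)
  }
})

test_that("untagged or random-without-seed input is refused", {
  t <- resolve_species(parse_newick("((a_1,b_1),(c_1,a_2));"), dm)
  expect_error(decompose(t), "tagged")
  expect_error(decompose(tag_rooted(t), prune_strategy = "random"), "seed")
})

test_that("output count, single-labeling and species conservation hold on random families", {
  ds <- sim_dataset(60, seed = 91, dup = 0.12, loss = 0.1)
  tagged <- sim_tagged_trees(ds)
  for (tt in tagged) {
    D <- discoq:::n_duplication_nodes(tt)
    d <- decompose(tt, "disco")
    dr <- decompose(tt, "disco-r")
    expect_equal(length(d$outputs), D + 1L)
    expect_equal(length(dr$outputs), D + 1L)
    for (o in c(d$outputs, dr$outputs))
      expect_true(check_single_labeled(o))
    # DISCO-R never loses a species: the backbone alone carries them all
    backbone <- dr$outputs[[length(dr$outputs)]]
    expect_setequal(tree_species(backbone), unique(tree_species(tt)))
  }
})

test_that("regraft-then-restrict recovers the plain backbone", {
  ds <- sim_dataset(40, seed = 17, dup = 0.12, loss = 0.1)
  tagged <- sim_tagged_trees(ds, min_leaves = 4)
  checked <- 0L
  for (tt in tagged) {
    d <- decompose(tt, "disco")
    dr <- decompose(tt, "disco-r")
    if (!identical(sub(":.*", "", d$provenance), sub(":.*", "", dr$provenance)) ||
        !identical(d$provenance, dr$provenance)) next  # pruning choices diverged
    bb <- d$outputs[[length(d$outputs)]]
    bbr <- dr$outputs[[length(dr$outputs)]]
    if (n_leaves(bb) < 4) next
    keep_sp <- tree_species(bb)
    restricted <- discoq:::node_drop_species(bbr$root,
                                             setdiff(tree_species(bbr), keep_sp))
    restricted <- discoq:::new_gene_tree(restricted, rooted = TRUE)
    expect_equal(rf_distance(restricted, bb)$rf_raw, 0)
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("random pruning is reproducible given its seed", {
  fix <- fig1_tagged()
  a <- decompose(fix, "disco", prune_strategy = "random", seed = 5)
  b <- decompose(fix, "disco", prune_strategy = "random", seed = 5)
  expect_identical(lapply(a$outputs, write_newick), lapply(b$outputs, write_newick))
})
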