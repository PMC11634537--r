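single_copy <- function(nwk) resolve_species(parse_newick(nwk), identity_mapping())

test_that("the exact solver picks the dominant quartet and satisfies self-tables", {
  tab <- quartet_table(c("a,b|c,d" = 5, "a,c|b,d" = 2))
  r <- exact_wmqc(tab, c("a", "b", "c", "d"))
  expect_equal(r$satisfied_weight, 5)
  expect_equal(induced_quartet(r$tree, c("a", "b", "c", "d")), "a,b|c,d")

  # a table from k copies of one tree returns that tree with score 1
  t <- single_copy("((a,(b,c)),((d,e),(f,g)));")
  for (k in c(1, 3)) {
    tab <- gtf_table(rep(list(t), k))
    ex <- exact_wmqc(tab, letters[1:7])
    expect_equal(ex$normalized_score, 1)
    expect_equal(rf_distance(ex$tree, t)$rf_raw, 0)
    he <- heuristic_wmqc(tab, letters[1:7], seed = 2)
    expect_equal(he$normalized_score, 1)
    expect_equal(rf_distance(he$tree, t)$rf_raw, 0)
  }
  expect_error(exact_wmqc(quartet_table(), letters[1:3]), "4 <= ")
  expect_error(exact_wmqc(quartet_table(), letters[1:10]), "<= 9")
})

test_that("the exact solver matches an exhaustive independent topology scan", {
  set.seed(21)
  for (rep in 1:2) {
    keys <- replicate(12, {
      sp <- sample(letters[1:7], 4)
      discoq:::canonical_quartet(sp[1:2], sp[3:4])
    })
    w <- sample(1:9, 12, replace = TRUE)
    tab <- quartet_table(stats::setNames(as.numeric(w), keys))
    r <- exact_wmqc(tab, letters[1:7])
    at <- phangorn::allTrees(7, rooted = FALSE, tip.label = letters[1:7])
    sc <- vapply(at, function(ph)
      quartet_score(discoq:::phylo_to_gene_tree(ph), tab)$satisfied_weight,
      numeric(1))
    expect_equal(r$satisfied_weight, max(sc))
  }
})

test_that("the exact solver is invariant under taxon relabeling", {
  set.seed(33)
  t <- rand_tree(6, labels = letters[1:6])
  tab <- gtf_table(list(t, rand_tree(6, labels = letters[1:6])))
  r1 <- exact_wmqc(tab, letters[1:6])
  perm <- stats::setNames(LETTERS[6:1], letters[1:6])
  relkeys <- vapply(names(tab), function(k) {
    p <- discoq:::parse_quartet_key(k)
    discoq:::canonical_quartet(unname(perm[p$p1]), unname(perm[p$p2]))
  }, "")
  tab2 <- quartet_table(stats::setNames(as.numeric(tab), relkeys))
  r2 <- exact_wmqc(tab2, LETTERS[1:6])
  expect_equal(r2$satisfied_weight, r1$satisfied_weight)
  # relabelling r1's optimum must attain the same weight on the relabelled
  # table (the optimum itself need not be unique)
  relabelled <- parse_newick(
    vapply(strsplit(write_newick(r1$tree, labels = "species"), "")[[1]],
           function(ch) if (ch %in% names(perm)) perm[[ch]] else ch, "") |>
      paste(collapse = ""))
  relabelled <- resolve_species(relabelled, identity_mapping())
  expect_equal(quartet_score(relabelled, tab2)$satisfied_weight,
               r2$satisfied_weight)
})

test_that("quartet scores equal a brute-force per-quartet recount", {
  set.seed(55)
  t <- rand_tree(7, labels = letters[1:7])
  keys <- replicate(10, {
    sp <- sample(letters[1:7], 4)
    discoq:::canonical_quartet(sp[1:2], sp[3:4])
  })
  tab <- quartet_table(stats::setNames(rep(2, 10), keys))
  got <- quartet_score(t, tab)
  manual <- 0
  for (k in names(tab)) {
    p <- discoq:::parse_quartet_key(k)
    if (oracle_quartet(t, c(p$p1, p$p2)) == k) manual <- manual + unclass(tab)[[k]]
  }
  expect_equal(got$satisfied_weight, manual)
  expect_equal(got$normalized_score, manual / sum(tab))

  # degenerate scores
  expect_equal(quartet_score(single_copy("((a,b),(c,d));"),
                             quartet_table(c("a,b|c,d" = 4)))$normalized_score, 1)
  expect_equal(quartet_score(single_copy("((a,b),(c,d));"),
                             quartet_table(c("a,c|b,d" = 4)))$normalized_score, 0)
  # species absent from the tree fall out of the denominator
  s <- quartet_score(single_copy("((a,b),(c,d));"),
                     quartet_table(c("a,b|c,d" = 4, "a,b|c,z" = 9)))
  expect_equal(s$normalized_score, 1)
})

test_that("the heuristic returns valid seeded-deterministic trees bounded by the exact optimum", {
  set.seed(77)
  taxa <- letters[1:8]
  keys <- replicate(30, {
    sp <- sample(taxa, 4)
    discoq:::canonical_quartet(sp[1:2], sp[3:4])
  })
  tab <- quartet_table(stats::setNames(as.numeric(sample(1:5, 30, TRUE)), keys))

  h1 <- heuristic_wmqc(tab, taxa, seed = 9)
  h2 <- heuristic_wmqc(tab, taxa, seed = 9)
  expect_equal(write_newick(h1$tree, labels = "species"),
               write_newick(h2$tree, labels = "species"))
  expect_setequal(tree_species(h1$tree), taxa)
  expect_true(discoq:::tree_is_binary(h1$tree))

  ex <- exact_wmqc(tab, taxa)
  expect_lte(h1$satisfied_weight, ex$satisfied_weight)

  # at least as good as a random resolution baseline
  base <- quartet_score(rand_tree(8, labels = taxa), tab)
  expect_gte(h1$satisfied_weight, base$satisfied_weight)
})
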