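quartet_sp <- "(((A:1,B:1):1,C:2):1,D:3);"

test_that("zero rates reproduce the species tree and single-copy families", {
  p <- dlcoal_params(quartet_sp, 0, 0, pop_size = 1, n_genes = 5, seed = 3)
  lt <- simulate_locus_tree(p, seed = 4)
  expect_false(lt$extinct)
  expect_equal(lt$n_duplications, 0L)

  ds <- generate_dataset(p)
  expect_equal(ds$n_redraws, 0L)
  for (g in ds$gene_trees) {
    expect_equal(n_leaves(g), 4L)
    expect_true(check_single_labeled(g))
  }
})

test_that("datasets are byte-identical across reruns of the same seed", {
  p <- dlcoal_params(quartet_sp, 0.1, 0.1, pop_size = 1, n_genes = 15, seed = 12)
  a <- generate_dataset(p)
  b <- generate_dataset(p)
  expect_identical(vapply(a$gene_trees, write_newick, ""),
                   vapply(b$gene_trees, write_newick, ""))
  expect_identical(a$n_redraws, b$n_redraws)
})

test_that("overwhelming loss reports extinction instead of an empty tree", {
  p <- dlcoal_params(quartet_sp, 0, 5, pop_size = 1, n_genes = 1, seed = 2)
  set.seed(2)
  res <- replicate(20, simulate_locus_tree(p)$extinct)
  expect_true(any(res))
  ext <- simulate_locus_tree(p, seed = 6)
  if (ext$extinct) expect_error(simulate_gene_tree(ext, 1), "extinct")
})

test_that("duplication counts match the small-rate Poisson expectation", {
  # E[duplications] ~ dup_rate * total species-tree length (= 9) at small rates
  rate <- 0.01
  p <- dlcoal_params(quartet_sp, rate, 0, pop_size = 1, n_genes = 1, seed = 0)
  set.seed(123)
  counts <- replicate(3000, simulate_locus_tree(p)$n_duplications)
  expected <- rate * 9
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("pairwise coalescence times have the neutral expectation", {
  # two species diverging t generations ago: E[tree height] = t + N
  p <- dlcoal_params("(A:3,B:3);", 0, 0, pop_size = 5, n_genes = 400, seed = 9)
  ds <- generate_dataset(p)
  # the root's child edges run from the coalescence down to each leaf, so
  # their length is 3 + X with X ~ Exp(1/N)
  x <- vapply(ds$gene_trees, function(g) g$root$children[[1]]$length, numeric(1)) - 3
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 5), 3 * se)
})

test_that("a surviving duplication yields a multi-copy family that tags correctly", {
  p <- dlcoal_params(quartet_sp, 0.15, 0, pop_size = 1, n_genes = 40, seed = 77)
  ds <- generate_dataset(p)
  dups <- vapply(ds$locus_trees, `[[`, integer(1), "n_duplications")
  i <- which(dups == 1L)[1]
  expect_false(is.na(i))
  g <- resolve_species(ds$gene_trees[[i]], ds$mapping)
  expect_false(check_single_labeled(g))
  tagged <- tag_rooted(g)
  expect_gte(discoq:::n_duplication_nodes(tagged), 1L)
})

test_that("species-quartet frequencies under pure ILS obey the coalescent ranking", {
  # internal branch 1 coalescent unit: matching topology clearly dominant
  p <- dlcoal_params(quartet_sp, 0, 0, pop_size = 1, n_genes = 600, seed = 101)
  ds <- generate_dataset(p)
  tops <- vapply(ds$gene_trees, function(g)
    induced_quartet(g, c("A", "B", "C", "D")), "")
  freq <- table(tops) / length(tops)
  expect_equal(names(which.max(freq)), "A,B|C,D")
})
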