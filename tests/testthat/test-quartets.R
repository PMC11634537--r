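dm <- delimiter_mapping("_")

single_copy <- function(nwk) resolve_species(parse_newick(nwk), identity_mapping())

test_that("induced quartets follow the restricted topology", {
  expect_equal(induced_quartet(single_copy("((a,b),(c,d));"), c("a", "b", "c", "d")),
               "a,b|c,d")
  expect_equal(induced_quartet(single_copy("(((a,b),c),d);"), c("a", "b", "c", "d")),
               "a,b|c,d")
  # the DISCO-R backbone of the worked example places e next to h
  bbr <- decompose(fig1_tagged(), "disco-r")$outputs[[2]]
  expect_equal(induced_quartet(bbr, c("a", "e", "c", "d")), "a,e|c,d")
  expect_error(induced_quartet(single_copy("((a,b),(c,d));"), c("a", "b", "c", "z")),
               "absent")
})

test_that("gtf weights count inducing trees and match a brute-force recount", {
  t1 <- single_copy("((a,b),(c,d));")
  expect_equal(unclass(gtf_table(list(t1)))[["a,b|c,d"]], 1)
  expect_equal(unclass(gtf_table(list(t1, t1)))[["a,b|c,d"]], 2)

  t2 <- single_copy("((a,c),(b,d));")
  tab <- gtf_table(list(t1, t2))
  expect_equal(unname(unclass(tab)[c("a,b|c,d", "a,c|b,d")]), c(1, 1))

  # brute-force oracle on random single-copy trees (<= 12 species)
  set.seed(5)
  trees <- c(lapply(c(6, 9, 12), rand_tree),
             list(single_copy("((a,b),((s1,s2),(s3,s4)));")))
  expect_identical(unclass(gtf_table(trees)), unclass(oracle_gtf(trees)))

  # weights over each 4-set sum to the number of trees containing it
  tab <- gtf_table(trees)
  fours <- vapply(names(tab), function(k) {
    p <- discoq:::parse_quartet_key(k); paste(sort(c(p$p1, p$p2)), collapse = ",")
  }, "")
  per4 <- tapply(unclass(tab), fours, sum)
  for (f in names(per4)) {
    sp4 <- strsplit(f, ",")[[1]]
    n_containing <- sum(vapply(trees, function(t) all(sp4 %in% tree_species(t)), TRUE))
    expect_equal(unname(per4[[f]]), n_containing)
  }

  expect_error(gtf_table(list(resolve_species(parse_newick("(x_1,(x_2,(y_1,z_1)));"), dm))),
               "single-labeled")
})

test_that("speciation-driven quartets match the worked example's classification", {
  fix <- fig1_tagged()
  s <- sq_set(fix)
  # SQs the plain decomposition misses
  expect_true(all(c("a,c|d,e", "a,h|d,e", "a,b|e,p", "a,b|h,p") %in% s))
  # induced but not speciation-driven
  expect_false("a,e|c,d" %in% s)
  expect_false("a,d|e,h" %in% s)

  # in a single-copy all-speciation tree every induced quartet is an SQ
  t <- tag_rooted(rand_tree(7))
  expect_setequal(sq_set(t), covered_quartets(list(t)))
})

test_that("quartet coverage of decompositions matches the worked example", {
  fix <- fig1_tagged()
  cov_d <- covered_quartets(decompose(fix, "disco"))
  cov_r <- covered_quartets(decompose(fix, "disco-r"))
  expect_false(any(c("a,b|e,p", "a,b|h,p") %in% cov_d))
  expect_true(all(c("a,b|e,p", "a,b|h,p", "b,p|e,h") %in% cov_r))
  expect_true(all(c("a,e|c,d", "a,d|e,h") %in% cov_r))   # introduced non-SQs
  expect_false(any(c("a,c|d,e", "a,h|d,e") %in% cov_r))  # still missed
  expect_equal(covered_quartets(list()), character(0))
})

test_that("weighted-quartet files round-trip exactly", {
  tab <- quartet_table(c("a,b|c,d" = 3, "a,c|b,e" = 1.5, "b,d|e,f" = 7))
  path <- withr::local_tempfile(fileext = ".wqt")
  write_quartets(tab, path)
  expect_equal(readLines(path)[1], "((a,b),(c,d)); 3")
  expect_identical(unclass(read_quartets(path)), unclass(tab))

  write_quartets(quartet_table(), path)
  expect_equal(length(readLines(path)), 0L)
  expect_equal(length(read_quartets(path)), 0L)
})

test_that("quartet keys canonicalize regardless of input order", {
  expect_equal(discoq:::canonical_quartet(c("d", "c"), c("b", "a")), "a,b|c,d")
  expect_equal(discoq:::canonical_quartet(c("b", "a"), c("d", "c")), "a,b|c,d")
  tab <- quartet_table(c("d,c|b,a" = 1, "a,b|c,d" = 2))
  expect_equal(unname(unclass(tab)[["a,b|c,d"]]), 3)
})
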