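test_that("the five-lineage fixture decomposes to the worked-example table", {
  tab <- decompose_periods(fixture_tree())
  expect_equal(tab$lineages, c(2, 3, 4, 5))
  expect_equal(tab$mutations, c(3, 6, 2, 5))
})

test_that("a star tree decomposes to a single tip period", {
  tab <- decompose_periods(read_mutation_tree("(a:1,b:2,c:3,d:4,e:5);"))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$lineages, 5)
  expect_equal(tab$mutations, 15)
})

test_that("pectinate decomposition matches the hand-enumerated assignment", {
  # (((a,b),c),d), one mutation per branch.  Direct: i4 <- a,b (2); i3 <- the
  # (ab)-(abc) internode (1); i2 <- the (abc)-root internode (1).  Spanning:
  # c over {4,3} weighted 2:1, d over {4,3,2} weighted 2:1:1.
  tab <- decompose_periods(read_mutation_tree("(((a:1,b:1):1,c:1):1,d:1);"))
  expect_equal(tab$lineages, c(2, 3, 4))
  expect_equal(tab$mutations,
               c(1 + 1 / 4, 1 + 1 / 3 + 1 / 4, 2 + 2 / 3 + 1 / 2),
               tolerance = 1e-12)
})

test_that("multifurcations skip intermediate lineage counts", {
  # the root joins (ab), c and d in a single event, so the i = 2 period is
  # never realised: periods are i = 4 (tips) and i = 3 only
  tab <- decompose_periods(read_mutation_tree("((a:1,b:1):2,c:1,d:1);"))
  expect_equal(tab$lineages, c(3, 4))
  expect_equal(sum(tab$mutations), 6)
})

test_that("apportionment follows the internode-weighted rule", {
  a <- apportion_spanning_mutations(4, c(3, 2), c(`3` = 6, `2` = 2))
  expect_equal(a$period, c(3, 2))
  expect_equal(a$mutations, c(3, 1))

  # zero mutations with no internode weights: uniform fallback, all zero
  expect_message(zero <- apportion_spanning_mutations(0, c(5, 4, 3)),
                 "uniformly")
  expect_true(all(zero$mutations == 0))

  expect_message(
    u <- apportion_spanning_mutations(5, c(4, 3, 2), c(`4` = 0, `3` = 0, `2` = 0)),
    "uniformly")
  expect_equal(u$mutations, rep(5 / 3, 3))
  expect_identical(sum(u$mutations), 5)  # conservation is exact

  expect_error(apportion_spanning_mutations(3, integer(0)), "empty")
})

test_that("decomposition conserves mutations on random genealogies", {
  for (tr in random_trees()) {
    tab <- decompose_periods(tr)
    expect_equal(sum(tab$mutations), sum(tr$phy$edge.length),
                 tolerance = 1e-12)
    expect_equal(max(tab$lineages), tr$n_tips)
  }
})

test_that("decomposition is invariant to child order in the Newick", {
  variants <- c("((((a:2,b:3):2,c:0):6,d:0):3,e:0);",
                "(e:0,(d:0,(c:0,(b:3,a:2):2):6):3);",
                "(e:0,((c:0,(a:2,b:3):2):6,d:0):3);")
  tabs <- lapply(variants, function(v)
    decompose_periods(read_mutation_tree(v)))
  for (tab in tabs[-1]) {
    expect_equal(tab$lineages, tabs[[1]]$lineages)
    expect_equal(tab$mutations, tabs[[1]]$mutations)
  }
})

test_that("a heavily mutated single-period tip branch triggers a warning", {
  expect_warning(decompose_periods(read_mutation_tree("(a:7,b:1);")),
                 "> 5")
})

test_that("period tables round-trip through TSV", {
  tab <- worked_example_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_period_table(tab, path)
  back <- read_period_table(path)
  expect_equal(back$lineages, tab$lineages)
  expect_equal(back$mutations, tab$mutations)
})

test_that("period-table validation catches malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines("period\tlineages\tmutations", path)
  expect_error(read_period_table(path), "empty")

  writeLines(c("period\tlineages\tmutations", "2\t3\t1"), path)
  expect_error(read_period_table(path), "disagree")

  writeLines(c("period\tlineages\tmutations", "1\t1\t4"), path)
  expect_error(read_period_table(path), ">= 2")

  writeLines(c("period\tlineages\tmutations", "2\t2\t-1"), path)
  expect_error(read_period_table(path), "non-negative")

  writeLines(c("period\tlineages\tmutations", "2\t2\tx"), path)
  expect_error(read_period_table(path), "non-numeric")

  # out-of-order rows are normalised with a message
  writeLines(c("period\tlineages\tmutations", "5\t5\t5", "2\t2\t3"), path)
  expect_message(tab <- read_period_table(path), "reordered")
  expect_equal(tab$lineages, c(2, 5))
})
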