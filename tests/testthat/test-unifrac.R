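test_that("weighted UniFrac is zero for identical compositions and one for
           disjoint tips", {
  # identical relative abundances (one sample is a scaled copy)
  counts <- rbind(c(2, 4, 6), c(1, 2, 3), c(9, 0, 1))
  tb <- toy_table(counts, line = c("HAS", "LAS", "HAS"))
  tree <- ape::read.tree(text = "((OTU_0001:1,OTU_0002:2):1,OTU_0003:3);")
  d <- as.matrix(weighted_unifrac(tb, tree))
  expect_equal(d[1, 2], 0)

  # two-leaf tree, samples on opposite leaves
  tb2 <- toy_table(rbind(c(5, 0), c(0, 7)), line = c("HAS", "LAS"))
  tree2 <- ape::read.tree(text = "(OTU_0001:0.3,OTU_0002:1.7);")
  expect_equal(as.matrix(weighted_unifrac(tb2, tree2))[1, 2], 1)
  expect_equal(as.matrix(weighted_unifrac(tb2, tree2, normalized = FALSE))[1, 2],
               0.3 + 1.7)
})

test_that("weighted UniFrac matches the brute-force branch oracle", {
  for (seed in 1:4) {
    inst <- random_unifrac_instance(seed)
    for (norm in c(TRUE, FALSE)) {
      mine <- as.matrix(weighted_unifrac(inst$table, inst$tree,
                                         normalized = norm))
      oracle <- oracle_unifrac(otu_counts(inst$table), inst$tree,
                               normalized = norm)
      expect_lt(max(abs(mine - oracle)), 1e-10)
    }
  }
})

test_that("weighted UniFrac behaves as a pseudometric", {
  for (seed in 5:7) {
    inst <- random_unifrac_instance(seed)
    d <- as.matrix(weighted_unifrac(inst$table, inst$tree))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1 + 1e-12))
    n <- nrow(d)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("tree tips absent from the table carry zero mass", {
  inst <- random_unifrac_instance(21)
  # drop two OTUs from the table; the tree keeps all its tips
  keep <- otu_ids(inst$table)[-c(2, 5)]
  sub <- inst$table[, c("sample_id", "line", "tissue", "replicate", keep)]
  mine <- as.matrix(weighted_unifrac(sub, inst$tree))
  oracle <- oracle_unifrac(otu_counts(sub), inst$tree)
  expect_lt(max(abs(mine - oracle)), 1e-10)
})

test_that("a table OTU missing from the tree is reported by name", {
  tb <- toy_table(rbind(c(1, 2), c(3, 4)))
  tree <- ape::read.tree(text = "(OTU_0001:1,OTU_9999:1);")
  expect_error(weighted_unifrac(tb, tree), "OTU_0002")
  tb0 <- toy_table(rbind(c(0, 0), c(1, 1)))
  tree2 <- ape::read.tree(text = "(OTU_0001:1,OTU_0002:1);")
  expect_error(weighted_unifrac(tb0, tree2), "all-zero")
})
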