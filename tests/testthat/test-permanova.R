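test_that("PERMANOVA p matches exhaustive enumeration on 6-sample toys", {
  for (seed in 1:5) {
    inst <- withr::with_seed(seed, {
      pts <- matrix(rnorm(12), ncol = 2)
      as.matrix(dist(pts))
    })
    rownames(inst) <- colnames(inst) <- paste0("s", 1:6)
    g <- rep(c("a", "b"), each = 3)
    res <- permanova(inst, g, n_permutations = 999, seed = seed)
    expect_identical(res$method, "exhaustive")
    expect_equal(res$p_value, oracle_permanova_p(inst, g))
  }
})

test_that("pseudo-F agrees with vegan's distance-based formulation", {
  inst <- random_unifrac_instance(11)
  d <- weighted_unifrac(inst$table, inst$tree)
  g <- inst$table$line
  res <- permanova(d, setNames(g, inst$table$sample_id),
                   n_permutations = 99, seed = 1)
  veg <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(res$pseudo_F, veg$F[1], tolerance = 1e-10)
})

test_that("degenerate all-zero distances give p = 1 and flagged F", {
  d <- matrix(0, 6, 6)
  rownames(d) <- colnames(d) <- paste0("s", 1:6)
  res <- permanova(d, rep(c("a", "b"), each = 3), n_permutations = 99)
  expect_true(res$degenerate)
  expect_true(is.na(res$pseudo_F))
  expect_equal(res$p_value, 1)
})

test_that("p-values are invariant to group renaming and sample order", {
  inst <- withr::with_seed(2, as.matrix(dist(matrix(rnorm(12), ncol = 2))))
  rownames(inst) <- colnames(inst) <- paste0("s", 1:6)
  g <- rep(c("a", "b"), each = 3)
  base <- permanova(inst, g, n_permutations = 999, seed = 3)
  renamed <- permanova(inst, ifelse(g == "a", "HAS", "LAS"),
                       n_permutations = 999, seed = 3)
  expect_equal(base$p_value, renamed$p_value)
  expect_equal(base$pseudo_F, renamed$pseudo_F)

  perm <- c(4, 1, 6, 2, 5, 3)
  reordered <- permanova(inst[perm, perm], g[perm],
                         n_permutations = 999, seed = 3)
  expect_equal(base$p_value, reordered$p_value)  # exhaustive: order-free
  expect_equal(base$pseudo_F, reordered$pseudo_F)
})

test_that("invalid groupings are rejected", {
  d <- as.matrix(dist(1:6))
  rownames(d) <- colnames(d) <- paste0("s", 1:6)
  expect_error(permanova(d, c("a", rep("b", 5)), n_permutations = 99),
               "fewer than 2")
  expect_error(permanova(d, rep("a", 6), n_permutations = 99), "two groups")
  expect_error(permanova(d, rep(c("a", "b"), 3), n_permutations = 10),
               ">= 99")
})
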