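test_that("simulation is deterministic and has the configured design", {
  cfg <- small_cfg(seed = 7)
  a <- simulate_otu_table(cfg)
  b <- simulate_otu_table(cfg)
  expect_identical(a, b)

  tb <- a$table
  expect_equal(nrow(tb), 2 * cfg$n_tissues * cfg$n_replicates)
  expect_equal(length(otu_ids(tb)), cfg$n_otus)
  expect_setequal(unique(tb$line), c("HAS", "LAS"))
  expect_equal(sort(unique(tb$tissue)),
               sort(c("duodenum", "jejunum", "ileum")))
  expect_true(all(otu_counts(tb) >= 0))
  expect_equal(dplyr::count(tb, line, tissue)$n, rep(6, 6))

  expr1 <- simulate_expression(a$table, a$truth, cfg)
  expr2 <- simulate_expression(b$table, b$truth, cfg)
  expect_identical(expr1, expr2)
})

test_that("exclusive OTUs are structural zeros in the other line only", {
  sim <- simulate_otu_table(small_cfg(seed = 3))
  m <- otu_counts(sim$table)
  las_rows <- sim$table$line == "LAS"
  for (o in sim$truth$exclusive_otus$HAS) {
    expect_true(all(m[las_rows, o] == 0))
    expect_gt(sum(m[!las_rows, o]), 0)
  }
  for (o in sim$truth$exclusive_otus$LAS) {
    expect_true(all(m[!las_rows, o] == 0))
    expect_gt(sum(m[las_rows, o]), 0)
  }
})

test_that("discriminative OTU means reflect the configured fold change", {
  cfg <- sim_config(seed = 1)
  sim <- simulate_otu_table(cfg)
  m <- otu_counts(sim$table)
  for (o in sim$truth$discriminative_otus) {
    boosted <- sim$truth$boosted_line[[o]]
    x_b <- m[sim$table$line == boosted, o]
    x_o <- m[sim$table$line != boosted, o]
    diff <- mean(x_b) - cfg$fold_change * mean(x_o)
    se <- sqrt(var(x_b) / 18 + cfg$fold_change^2 * var(x_o) / 18)
    expect_lt(abs(diff) / se, 3)
  }
})

test_that("null configuration yields approximately uniform NB-GLM p-values", {
  cfg <- sim_config(fold_change = 1, n_exclusive_per_line = 0, seed = 42)
  sim <- simulate_otu_table(cfg)
  res <- diff_abundance(filter_low_count(sim$table))
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("expression columns are TPM-normalized and track abundance class", {
  cfg <- small_cfg(seed = 5, expr_effect_size = 2, expr_noise_sd = 0.25)
  sim <- simulate_otu_table(cfg)
  expr <- simulate_expression(sim$table, sim$truth, cfg)
  sums <- rowSums(expr_values(expr))
  expect_true(all(abs(sums - 1e6) <= 1e-6 * 1e6))

  # linked genes shift upward with the abundance class of their OTU
  ok <- 0
  total <- 0
  for (o in names(sim$truth$linked_genes)) {
    cl <- discretize_abundance(
      tibble::tibble(sample_id = sim$table$sample_id,
                     count = sim$table[[o]]))
    ords <- class_ordinal(cl)
    hi <- names(ords)[ords == max(ords)]
    lo <- names(ords)[ords == min(ords)]
    if (length(hi) == 0 || length(lo) == 0) next
    m <- expr_values(expr)
    for (g in sim$truth$linked_genes[[o]]) {
      total <- total + 1
      if (mean(m[hi, g]) > mean(m[lo, g])) ok <- ok + 1
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("zero expression effect leaves linked genes unenriched", {
  cfg <- small_cfg(seed = 11, expr_effect_size = 0)
  sim <- simulate_otu_table(cfg)
  expr <- simulate_expression(sim$table, sim$truth, cfg)
  otu <- names(sim$truth$linked_genes)[1]
  cl <- discretize_abundance(
    tibble::tibble(sample_id = sim$table$sample_id,
                   count = sim$table[[otu]]), otu_id = otu)
  expect_false(cl$degenerate)
  ranked <- rank_genes(expr, cl)
  linked_ranks <- ranked$rank[ranked$gene %in% sim$truth$linked_genes[[otu]]]
  other_ranks <- ranked$rank[!ranked$gene %in% sim$truth$linked_genes[[otu]]]
  wt <- stats::wilcox.test(linked_ranks, other_ranks)
  expect_gt(wt$p.value, 0.01)
})

test_that("simulated trees are rooted binary with the requested tips", {
  tr2 <- simulate_tree(c("a", "b"), seed = 1)
  expect_equal(ape::Ntip(tr2), 2)
  expect_equal(tr2$Nnode, 1)

  ids <- sprintf("OTU_%04d", 1:450)
  tr <- simulate_tree(ids, seed = 1)
  nwk <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, nwk)
  parsed <- ape::read.tree(nwk)
  expect_equal(ape::Ntip(parsed), 450)
  expect_equal(parsed$Nnode, 449)
  expect_setequal(parsed$tip.label, ids)
  expect_true(all(parsed$edge.length > 0))
  expect_true(ape::is.rooted(parsed))

  expect_identical(ape::write.tree(simulate_tree(ids, seed = 1)),
                   ape::write.tree(simulate_tree(ids, seed = 1)))
  expect_false(identical(ape::write.tree(simulate_tree(ids, seed = 1)),
                         ape::write.tree(simulate_tree(ids, seed = 2))))
  expect_error(simulate_tree(c("a", "a")), "duplicate")
  expect_error(simulate_tree("a"), "at least 2")
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_otus = 10, n_discriminative = 8,
                          n_exclusive_per_line = 2), "exclusive")
  expect_error(sim_config(fold_change = 0.5), "fold_change")
  expect_error(sim_config(n_genes = 10, n_discriminative = 5,
                          n_linked_genes_per_otu = 10), "linked")
  expect_silent(sim_config(fold_change = 1))
})
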