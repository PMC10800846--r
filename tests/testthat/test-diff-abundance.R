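test_that("a single tested OTU has fdr and bonferroni equal to its p", {
  counts <- withr::with_seed(1, matrix(rnbinom(12, mu = 50, size = 2),
                                       ncol = 1))
  tb <- toy_table(counts)
  res <- diff_abundance(tb)
  expect_equal(res$fdr_p, res$p_value)
  expect_equal(res$bonferroni_p, res$p_value)
})

test_that("all-zero OTUs are excluded with a warning, not an error", {
  counts <- withr::with_seed(2, cbind(rnbinom(12, mu = 40, size = 2), 0L))
  tb <- toy_table(counts)
  expect_warning(res <- diff_abundance(tb), "all-zero")
  expect_equal(res$otu_id, "OTU_0001")
})

test_that("adjusted p-values match brute-force definitions", {
  sim <- simulate_otu_table(small_cfg(seed = 9))
  res <- suppressWarnings(diff_abundance(filter_low_count(sim$table)))
  expect_equal(res$fdr_p, oracle_bh(res$p_value), tolerance = 1e-12)
  expect_equal(res$bonferroni_p,
               pmin(1, length(res$p_value) * res$p_value),
               tolerance = 1e-12)
  expect_true(all(res$fdr_p >= 0 & res$fdr_p <= 1))
})

test_that("planted fold-4 OTUs are recovered and nulls mostly are not", {
  cfg <- sim_config(seed = 21)
  sim <- simulate_otu_table(cfg)
  res <- suppressWarnings(diff_abundance(filter_low_count(sim$table)))
  disc <- sim$truth$discriminative_otus
  hits <- res$otu_id[res$sig_fdr]
  expect_gte(mean(disc %in% hits), 0.8)
  nulls <- setdiff(res$otu_id,
                   c(disc, unlist(sim$truth$exclusive_otus)))
  expect_lte(mean(nulls %in% hits), 0.10)

  # effect direction: HAS-boosted OTUs have positive log2 fold change
  boosted_has <- names(sim$truth$boosted_line)[
    sim$truth$boosted_line == "HAS"]
  lfc <- res$log2_fc[match(boosted_has, res$otu_id)]
  expect_true(all(lfc > 0))
})

test_that("p-value ranking broadly agrees with edgeR's NB pipeline", {
  sim <- simulate_otu_table(small_cfg(seed = 13))
  tb <- filter_low_count(sim$table)
  res <- suppressWarnings(diff_abundance(tb))

  m <- t(otu_counts(tb))
  dge <- edgeR::DGEList(counts = m,
                        group = factor(tb$line, levels = c("LAS", "HAS")))
  dge <- edgeR::calcNormFactors(dge)
  design <- stats::model.matrix(~ factor(tb$line, levels = c("LAS", "HAS")))
  dge <- edgeR::estimateDisp(dge, design)
  fit <- edgeR::glmFit(dge, design)
  lrt <- edgeR::glmLRT(fit)
  edger_p <- lrt$table$PValue[match(res$otu_id, rownames(lrt$table))]

  expect_gt(cor(rank(res$p_value), rank(edger_p), method = "spearman"), 0.8)
  top_mine <- res$otu_id[order(res$p_value)][1:5]
  top_edger <- res$otu_id[order(edger_p)][1:5]
  expect_gte(length(intersect(top_mine, top_edger)), 3)
})
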