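expr_fixture <- function(seed = 1, n_genes = 30, n = 12) {
  withr::with_seed(seed, {
    m <- matrix(2^rnorm(n * n_genes, 8, 0.5), nrow = n)
    colnames(m) <- sprintf("GENE_%04d", seq_len(n_genes))
    m <- m / rowSums(m) * 1e6
    dplyr::bind_cols(tibble::tibble(sample_id = sprintf("s%02d", 1:n)),
                     tibble::as_tibble(m))
  })
}

classes_fixture <- function(n = 12) {
  counts <- rep(c(5, 50, 200), length.out = n)
  discretize_abundance(setNames(counts, sprintf("s%02d", 1:n)),
                       otu_id = "OTU_0001")
}

test_that("gene ranking puts a class-determined gene first and a constant
           gene last", {
  cl <- classes_fixture()
  expr <- expr_fixture()
  ords <- class_ordinal(cl)[expr$sample_id]
  expr$GENE_0001 <- 2^(6 + 3 * ords)          # deterministic in the class
  expr$GENE_0002 <- 500                        # constant
  ranked <- rank_genes(expr, cl)
  expect_equal(ranked$gene[1], "GENE_0001")
  y <- factor(as.character(cl$classes$class))
  expect_equal(ranked$info_gain[1], oracle_entropy(y), tolerance = 1e-10)
  expect_equal(ranked$info_gain[ranked$gene == "GENE_0002"], 0)
})

test_that("synthetic linked genes rank above background genes", {
  better <- vapply(1:10, function(s) {
    cfg <- small_cfg(seed = s + 300, expr_effect_size = 2,
                     expr_noise_sd = 0.25)
    sim <- simulate_otu_table(cfg)
    expr <- simulate_expression(sim$table, sim$truth, cfg)
    otu <- names(sim$truth$linked_genes)[1]
    cl <- discretize_abundance(
      tibble::tibble(sample_id = sim$table$sample_id,
                     count = sim$table[[otu]]), otu_id = otu)
    if (cl$degenerate) return(NA)
    ranked <- rank_genes(expr, cl)
    linked <- ranked$rank[ranked$gene %in% sim$truth$linked_genes[[otu]]]
    rest <- ranked$rank[!ranked$gene %in% sim$truth$linked_genes[[otu]]]
    median(linked) < median(rest)
  }, logical(1))
  expect_gte(mean(better, na.rm = TRUE), 0.95)
})

test_that("a perfectly encoding gene pins the best size to the smallest", {
  cl <- classes_fixture()
  expr <- expr_fixture(seed = 2)
  ords <- class_ordinal(cl)[expr$sample_id]
  expr$GENE_0001 <- 2^(6 + 3 * ords)
  res <- optimize_gene_list(expr, cl, size_grid = c(1, 4, 8), seed = 3)
  expect_equal(res$best_size, 1)
  expect_equal(res$best_accuracy, 1)
  expect_identical(res$best_genes, "GENE_0001")
  expect_equal(res$grid$size, c(1, 4, 8))
})

test_that("rare classes are merged for fold construction only", {
  counts <- setNames(c(0, rep(c(10, 100), length.out = 11)),
                     sprintf("s%02d", 1:12))
  cl <- discretize_abundance(counts, otu_id = "x")  # one Absent sample
  expr <- expr_fixture(seed = 5)
  res <- optimize_gene_list(expr, cl, size_grid = c(2, 4), seed = 1)
  expect_true(res$merged_classes)
  expect_true(is.finite(res$best_accuracy))
})

test_that("degenerate classes are refused with advice to exclude the OTU", {
  cl <- discretize_abundance(c(5, 5, 5, 5))
  expr <- expr_fixture(n = 4)
  expect_error(rank_genes(expr, cl), "exclude")
  expect_error(optimize_gene_list(expr, cl), "exclude")
})

test_that("gene-list export writes one file per OTU plus a summary", {
  cl <- classes_fixture()
  expr <- expr_fixture(seed = 7)
  res <- optimize_gene_list(expr, cl, size_grid = c(2, 4), seed = 2)
  out <- withr::local_tempdir()
  results <- list(OTU_0001 = res, OTU_0002 = res, OTU_0003 = NULL)
  summary <- export_gene_lists(results, out,
                               line_accuracy = c(OTU_0001 = 0.9))
  expect_equal(nrow(summary), 3)
  expect_equal(summary$status, c("ok", "ok", "degenerate"))
  expect_setequal(list.files(out),
                  c("genes_OTU_0001.txt", "genes_OTU_0002.txt",
                    "gene_list_summary.tsv"))
  expect_equal(readLines(file.path(out, "genes_OTU_0001.txt")),
               res$best_genes)
  expect_equal(sum(summary$status == "ok"), 2)
})
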