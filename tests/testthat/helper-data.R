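# Small fixtures built in code.

small_cfg <- function(seed = 1, ...) {
  sim_config(n_otus = 40, n_genes = 100, n_discriminative = 4,
             n_exclusive_per_line = 2, n_linked_genes_per_otu = 10,
             seed = seed, ...)
}

# OTU tibble from an explicit samples-by-OTUs matrix.
toy_table <- function(counts, line = NULL, tissue = "jejunum") {
  n <- nrow(counts)
  line <- line %||% rep(c("HAS", "LAS"), length.out = n)
  tb <- tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    line = line,
    tissue = rep(tissue, length.out = n),
    replicate = stats::ave(seq_len(n), line, FUN = seq_along)
  )
  colnames(counts) <- colnames(counts) %||%
    sprintf("OTU_%04d", seq_len(ncol(counts)))
  dplyr::bind_cols(tb, tibble::as_tibble(counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random (table, tree) instance for UniFrac checks.
random_unifrac_instance <- function(seed, n_samples = 8, n_otus = 12) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n_samples * n_otus, lambda = 8) +
                       rbinom(n_samples * n_otus, 1, 0.5),
                     nrow = n_samples)
    counts[rowSums(counts) == 0, 1] <- 1
    tb <- toy_table(counts)
    tree <- ape::rtree(n_otus, tip.label = otu_ids(tb))
    list(table = tb, tree = tree)
  })
}
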