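#' Simulate an OTU count table with planted line structure
#'
#' Generates a samples-by-OTUs negative-binomial count table for the
#' two-line, multi-tissue, replicated design described by [sim_config()].
#' Baseline per-OTU abundances are log-normal; planted discriminative and
#' exclusive OTUs are drawn from the abundant tail of that distribution
#' (emulating that the real signature taxa are dominant lactobacilli).
#' Discriminative OTUs have their mean multiplied by `fold_change` in one
#' line (alternating HAS/LAS across OTUs); exclusive OTUs have structural
#' zero mean in the other line. A mild log-normal tissue main effect and
#' log-normal per-sample depth factors (sdlog 0.3) are applied.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   * `table`: OTU tibble (columns `sample_id`, `line`, `tissue`,
#'     `replicate`, then one count column per OTU);
#'   * `truth`: ground-truth list with `discriminative_otus`,
#'     `boosted_line` (named by OTU), `exclusive_otus` (`$HAS`, `$LAS`) and
#'     `linked_genes` (named list, one disjoint gene set per discriminative
#'     OTU).
#' @examples
#' sim <- simulate_otu_table(sim_config(n_otus = 40, n_genes = 100, seed = 1))
#' dim(otu_counts(sim$table))
#' @export
simulate_otu_table <- function(config) {
  validate_sim_config(config)
  cfg <- config
  tissues <- tissue_names(cfg$n_tissues)
  lines <- c("HAS", "LAS")
  meta <- tidyr::expand_grid(line = lines, tissue = tissues,
                             replicate = seq_len(cfg$n_replicates)) |>
    mutate(sample_id = sprintf("%s%d_%s", .data$line, .data$replicate,
                               .data$tissue)) |>
    select("sample_id", "line", "tissue", "replicate")

  ids <- sprintf("OTU_%04d", seq_len(cfg$n_otus))
  gene_ids <- sprintf("GENE_%04d", seq_len(cfg$n_genes))
  n_samp <- nrow(meta)

  res <- with_seed(cfg$seed, {
    w <- rlnorm(cfg$n_otus, meanlog = 0, sdlog = 1.5)
    planted_n <- cfg$n_discriminative + 2L * cfg$n_exclusive_per_line
    planted_idx <- sample(cfg$n_otus, planted_n)
    disc_idx <- head(planted_idx, cfg$n_discriminative)
    excl_has_idx <- planted_idx[cfg$n_discriminative +
                                  seq_len(cfg$n_exclusive_per_line)]
    excl_las_idx <- tail(planted_idx, cfg$n_exclusive_per_line)
    # planted OTUs sit in the abundant tail so they are detectable signal
    w[planted_idx] <- rlnorm(planted_n, meanlog = 3, sdlog = 0.7)

    mu0 <- w / sum(w) * cfg$library_size_mean
    tissue_mult <- matrix(rlnorm(cfg$n_otus * cfg$n_tissues, 0, 0.25),
                          nrow = cfg$n_otus)
    line_mult <- matrix(1, nrow = cfg$n_otus, ncol = 2,
                        dimnames = list(NULL, lines))
    boosted <- rep(lines, length.out = cfg$n_discriminative)
    if (cfg$n_discriminative > 0) {
      line_mult[cbind(disc_idx, match(boosted, lines))] <- cfg$fold_change
    }
    if (cfg$n_exclusive_per_line > 0) {
      line_mult[excl_has_idx, "LAS"] <- 0
      line_mult[excl_las_idx, "HAS"] <- 0
    }
    depth <- rlnorm(n_samp, 0, 0.3)

    counts <- matrix(0L, nrow = n_samp, ncol = cfg$n_otus,
                     dimnames = list(meta$sample_id, ids))
    for (s in seq_len(n_samp)) {
      mu <- mu0 * tissue_mult[, match(meta$tissue[s], tissues)] *
        line_mult[, meta$line[s]] * depth[s]
      counts[s, ] <- if (cfg$nb_dispersion > 0) {
        rnbinom(cfg$n_otus, mu = mu, size = 1 / cfg$nb_dispersion)
      } else {
        rpois(cfg$n_otus, mu)
      }
    }

    linked <- list()
    if (cfg$n_discriminative > 0 && cfg$n_linked_genes_per_otu > 0) {
      pool <- sample(gene_ids)
      for (k in seq_len(cfg$n_discriminative)) {
        take <- pool[(k - 1L) * cfg$n_linked_genes_per_otu +
                       seq_len(cfg$n_linked_genes_per_otu)]
        linked[[ids[disc_idx[k]]]] <- sort(take)
      }
    }
    list(counts = counts, disc = ids[disc_idx],
         boosted = setNames(boosted, ids[disc_idx]),
         excl_has = ids[excl_has_idx], excl_las = ids[excl_las_idx],
         linked = linked)
  })

  table <- bind_cols(meta, as_tibble(res$counts))
  truth <- list(
    discriminative_otus = res$disc,
    boosted_line = res$boosted,
    exclusive_otus = list(HAS = res$excl_has, LAS = res$excl_las),
    linked_genes = res$linked
  )
  list(table = table, truth = truth)
}

tissue_names <- function(n) {
  base <- c("duodenum", "jejunum", "ileum")
  if (n <= 3) head(base, n) else c(base, sprintf("tissue%d", 4:n))
}

#' Simulate a rooted phylogeny over a set of OTU identifiers
#'
#' Draws a random coalescent topology (via [ape::rcoal()]) with strictly
#' positive branch lengths; any rooted tree with positive lengths is a valid
#' input for weighted UniFrac.
#'
#' @param otu_ids Character vector of at least two unique OTU identifiers.
#' @param seed Integer seed; the emitted Newick string is identical per seed.
#' @return A rooted binary `phylo` object whose tip labels are `otu_ids`.
#' @examples
#' tr <- simulate_tree(c("OTU_1", "OTU_2", "OTU_3"), seed = 1)
#' @export
simulate_tree <- function(otu_ids, seed = 1) {
  otu_ids <- as.character(otu_ids)
  if (length(otu_ids) < 2) abort("need at least 2 OTU ids.")
  if (anyDuplicated(otu_ids)) abort("duplicate OTU ids.")
  with_seed(as.integer(seed), ape::rcoal(length(otu_ids), tip.label = otu_ids))
}

#' Simulate a TPM expression matrix coupled to OTU abundance classes
#'
#' For every OTU with linked genes in `truth$linked_genes`, the linked genes'
#' log2 expression shifts by `expr_effect_size` per ordinal step of that
#' OTU's discretized abundance class (Absent < Low < High, or
#' Low < Medium < High when the OTU is present in every sample),
#' discretized within each tissue slice so the planted link matches the
#' tissue-wise downstream analysis; all other genes are class-independent
#' log-normal noise. Each sample is scaled to a total of 10^6
#' (transcripts-per-million convention).
#'
#' @param table OTU tibble from [simulate_otu_table()].
#' @param truth Matching ground-truth list.
#' @param config The [sim_config()] used to generate `table`.
#' @return An expression tibble (`sample_id` plus one column per gene).
#' @export
simulate_expression <- function(table, truth, config) {
  validate_sim_config(config)
  check_otu_table(table)
  cfg <- config
  gene_ids <- sprintf("GENE_%04d", seq_len(cfg$n_genes))
  linked <- truth$linked_genes %||% list()
  missing_otu <- setdiff(names(linked), otu_ids(table))
  if (length(missing_otu) > 0) {
    abort(paste0("linked OTUs absent from `table`: ",
                 paste(missing_otu, collapse = ", ")))
  }
  bad_genes <- setdiff(unlist(linked, use.names = FALSE), gene_ids)
  if (length(bad_genes) > 0) {
    abort("truth$linked_genes names genes outside the configured gene set.")
  }
  n_samp <- nrow(table)

  # Per-sample ordinal class (0, 1, 2) of each linked OTU, discretized
  # within each tissue slice: downstream analysis works tissue-by-tissue,
  # and tissue effects would otherwise let one tissue's abundances swamp
  # another's classes.
  ords <- matrix(0, nrow = n_samp, ncol = length(linked),
                 dimnames = list(table$sample_id, names(linked)))
  for (otu in names(linked)) {
    for (tis in unique(table$tissue)) {
      rows <- table$tissue == tis
      x <- table[[otu]][rows]
      if (all(x == 0)) next  # ordinal 0 throughout the slice
      cl <- discretize_abundance(
        tibble(sample_id = table$sample_id[rows], count = x)
      )
      ords[rows, otu] <- class_ordinal(cl)
    }
  }

  expr <- with_seed(derive_seed(cfg$seed, "expression"), {
    baseline <- runif(cfg$n_genes, min = 3, max = 9)
    log2x <- matrix(rnorm(n_samp * cfg$n_genes, sd = cfg$expr_noise_sd),
                    nrow = n_samp) + rep(baseline, each = n_samp)
    for (otu in names(linked)) {
      g <- match(linked[[otu]], gene_ids)
      log2x[, g] <- log2x[, g] + cfg$expr_effect_size * ords[, otu]
    }
    x <- 2^log2x
    x / rowSums(x) * 1e6
  })
  dimnames(expr) <- list(table$sample_id, gene_ids)
  bind_cols(tibble(sample_id = table$sample_id), as_tibble(expr))
}

#' Simulate a complete coupled study
#'
#' Convenience wrapper generating the OTU table, the phylogeny over its OTUs
#' and the coupled expression matrix in one call.
#'
#' @param config A [sim_config()].
#' @return A list with `table`, `tree`, `expression`, `truth` and `config`.
#' @examples
#' study <- simulate_study(sim_config(n_otus = 40, n_genes = 100, seed = 7))
#' @export
simulate_study <- function(config = sim_config()) {
  sim <- simulate_otu_table(config)
  tree <- simulate_tree(otu_ids(sim$table),
                        seed = derive_seed(config$seed, "tree"))
  expr <- simulate_expression(sim$table, sim$truth, config)
  list(table = sim$table, tree = tree, expression = expr,
       truth = sim$truth, config = config)
}
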