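#' Configuration for the coupled synthetic study generator
#'
#' Defines the simulated study design: two chicken lines (HAS/LAS), three
#' small-intestinal tissues, six biological replicates per line and tissue,
#' negative-binomial OTU counts with planted line-discriminative and
#' line-exclusive OTUs, and log-normal gene expression in which genes linked
#' to a discriminative OTU shift with that OTU's discretized abundance class.
#'
#' @param n_tissues Number of tissues (default 3: duodenum, jejunum, ileum).
#' @param n_replicates Biological replicates per line and tissue (default 6).
#' @param n_otus Total number of OTUs (default 450, the post-filter size the
#'   pipeline is designed around).
#' @param n_discriminative Number of planted line-discriminative OTUs whose
#'   mean is multiplied by `fold_change` in one line (default 20).
#' @param n_exclusive_per_line Number of OTUs per line with structural-zero
#'   mean in the other line (default 5).
#' @param fold_change Mean multiplier for discriminative OTUs in the boosted
#'   line; `1` plants no line effect (default 4).
#' @param nb_dispersion Negative-binomial dispersion phi, with
#'   `var = mu + phi * mu^2`; `0` gives Poisson counts (default 0.25).
#' @param library_size_mean Expected sequencing depth per sample (default
#'   50000); per-sample depth factors are log-normal with sdlog 0.3.
#' @param n_genes Number of genes in the expression matrix (default 2000).
#' @param n_linked_genes_per_otu Genes linked to each discriminative OTU
#'   (default 50); linked sets are disjoint.
#' @param expr_effect_size Log2-scale expression shift per ordinal step of
#'   the linked OTU's abundance class (default 2).
#' @param expr_noise_sd Log2-scale residual standard deviation (default 0.25).
#' @param seed Integer seed; identical configurations generate byte-identical
#'   data.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_otus = 60, n_genes = 200, seed = 1)
#' @export
sim_config <- function(n_tissues = 3,
                       n_replicates = 6,
                       n_otus = 450,
                       n_discriminative = 20,
                       n_exclusive_per_line = 5,
                       fold_change = 4,
                       nb_dispersion = 0.25,
                       library_size_mean = 50000,
                       n_genes = 2000,
                       n_linked_genes_per_otu = 50,
                       expr_effect_size = 2,
                       expr_noise_sd = 0.25,
                       seed = 1) {
  cfg <- list(
    n_lines = 2L,
    n_tissues = as.integer(n_tissues),
    n_replicates = as.integer(n_replicates),
    n_otus = as.integer(n_otus),
    n_discriminative = as.integer(n_discriminative),
    n_exclusive_per_line = as.integer(n_exclusive_per_line),
    fold_change = as.double(fold_change),
    nb_dispersion = as.double(nb_dispersion),
    library_size_mean = as.double(library_size_mean),
    n_genes = as.integer(n_genes),
    n_linked_genes_per_otu = as.integer(n_linked_genes_per_otu),
    expr_effect_size = as.double(expr_effect_size),
    expr_noise_sd = as.double(expr_noise_sd),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  bad <- function(msg) abort(paste0("invalid simulation config: ", msg))
  if (cfg$n_tissues < 1) bad("n_tissues must be >= 1")
  if (cfg$n_replicates < 1) bad("n_replicates must be >= 1")
  if (cfg$n_otus < 2) bad("n_otus must be >= 2")
  if (cfg$n_discriminative < 0 || cfg$n_exclusive_per_line < 0) {
    bad("planted OTU counts must be non-negative")
  }
  if (cfg$n_discriminative + 2L * cfg$n_exclusive_per_line > cfg$n_otus) {
    bad("n_discriminative + 2 * n_exclusive_per_line must be <= n_otus")
  }
  if (cfg$fold_change < 1) bad("fold_change must be >= 1")
  if (cfg$nb_dispersion < 0) bad("nb_dispersion must be >= 0")
  if (cfg$library_size_mean <= 0) bad("library_size_mean must be positive")
  if (cfg$n_genes < 1) bad("n_genes must be >= 1")
  if (cfg$n_linked_genes_per_otu < 0) bad("n_linked_genes_per_otu must be >= 0")
  if (cfg$n_discriminative * cfg$n_linked_genes_per_otu > cfg$n_genes) {
    bad("disjoint linked-gene sets need n_discriminative * n_linked_genes_per_otu <= n_genes")
  }
  if (cfg$expr_noise_sd < 0) bad("expr_noise_sd must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  design : 2 lines x %d tissues x %d replicates (%d samples)\n",
              x$n_tissues, x$n_replicates, 2L * x$n_tissues * x$n_replicates))
  cat(sprintf("  otus   : %d (%d discriminative @ fold %.2g, %d exclusive/line)\n",
              x$n_otus, x$n_discriminative, x$fold_change,
              x$n_exclusive_per_line))
  cat(sprintf("  genes  : %d (%d linked/OTU, effect %.2g log2/step, noise sd %.2g)\n",
              x$n_genes, x$n_linked_genes_per_otu, x$expr_effect_size,
              x$expr_noise_sd))
  cat(sprintf("  counts : NB dispersion %.3g, mean depth %g, seed %d\n",
              x$nb_dispersion, x$library_size_mean, x$seed))
  invisible(x)
}
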