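#' Weighted UniFrac distances between samples
#'
#' For every pair of samples, raw weighted UniFrac is
#' `sum_b len_b * |A_b - B_b|`, where the sum runs over the branches of the
#' phylogeny and `A_b` (`B_b`) is the fraction of sample A's (B's) total
#' count carried by tips descending from branch `b`. The normalized variant
#' divides each pair by its maximum attainable value,
#' `sum_b len_b * (A_b + B_b)`, so distances lie in `[0, 1]`.
#'
#' @param table An OTU tibble; every OTU column must be a tip of `tree` and
#'   every sample must have at least one nonzero count.
#' @param tree A rooted `phylo` object with branch lengths.
#' @param normalized Divide by the per-pair maximum (default `TRUE`).
#' @return A `dist` object labelled by sample id.
#' @examples
#' sim <- simulate_otu_table(sim_config(n_otus = 12, n_genes = 10,
#'                                      n_discriminative = 2,
#'                                      n_exclusive_per_line = 0,
#'                                      n_linked_genes_per_otu = 5, seed = 1))
#' tr <- simulate_tree(otu_ids(sim$table), seed = 2)
#' d <- weighted_unifrac(sim$table, tr)
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  check_otu_table(table)
  stopifnot(inherits(tree, "phylo"))
  ids <- otu_ids(table)
  missing <- setdiff(ids, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("OTU(s) missing from tree: ",
                 paste(missing, collapse = ", ")))
  }
  m <- otu_counts(table)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    abort(paste0("sample(s) with all-zero counts: ",
                 paste(rownames(m)[tot == 0], collapse = ", ")))
  }
  p <- m / tot

  mass <- branch_mass(p, tree)   # samples x edges
  len <- tree$edge.length
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(len * abs(mass[i, ] - mass[j, ]))
      if (normalized) {
        den <- sum(len * (mass[i, ] + mass[j, ]))
        d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
      } else {
        d[i, j] <- d[j, i] <- num
      }
    }
  }
  stats::as.dist(d)
}

# Fraction of each sample's mass descending from each edge: postorder
# accumulation of tip masses up the tree. Rows = samples, cols = edges
# (in tree$edge order).
branch_mass <- function(p, tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  node_mass <- matrix(0, nrow = nrow(p), ncol = nn)
  present <- intersect(tree$tip.label, colnames(p))
  node_mass[, match(present, tree$tip.label)] <- p[, present, drop = FALSE]
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    parent <- po$edge[k, 1]
    child <- po$edge[k, 2]
    node_mass[, parent] <- node_mass[, parent] + node_mass[, child]
  }
  node_mass[, tree$edge[, 2], drop = FALSE]
}
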