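# Independent oracles used to check the package's implementations.
# These deliberately use different algorithms / code paths.

# Brute-force weighted UniFrac: enumerate every branch, find its descendant
# tip set by walking the edge list, and sum |A - B| (and A + B) explicitly.
oracle_unifrac <- function(counts, tree, normalized = TRUE) {
  p <- counts / rowSums(counts)
  ntip <- length(tree$tip.label)
  descendant_tips <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, descendant_tips))
  }
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- 0
      den <- 0
      for (e in seq_len(nrow(tree$edge))) {
        tips <- intersect(descendant_tips(tree$edge[e, 2]), colnames(p))
        a <- sum(p[i, tips])
        b <- sum(p[j, tips])
        num <- num + tree$edge.length[e] * abs(a - b)
        den <- den + tree$edge.length[e] * (a + b)
      }
      d[i, j] <- d[j, i] <- if (normalized) num / den else num
    }
  }
  d
}

# Exhaustive PERMANOVA for two groups: enumerate every assignment of the
# given sizes with combn and recompute the pseudo-F from first principles.
oracle_permanova_p <- function(dm, groups) {
  d2 <- as.matrix(dm)^2
  n <- nrow(d2)
  g <- factor(groups)
  sizes <- table(g)
  stopifnot(length(sizes) == 2)
  f_of <- function(idx_a) {
    idx_b <- setdiff(seq_len(n), idx_a)
    ss_t <- sum(d2) / (2 * n)
    ss_w <- sum(d2[idx_a, idx_a]) / (2 * length(idx_a)) +
      sum(d2[idx_b, idx_b]) / (2 * length(idx_b))
    ((ss_t - ss_w) / 1) / (ss_w / (n - 2))
  }
  obs <- f_of(which(g == levels(g)[1]))
  all_f <- apply(combn(n, sizes[1]), 2, f_of)
  mean(all_f >= obs - 1e-12)
}

# Benjamini-Hochberg step-up computed directly from its definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, m * p[o[k]] / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# Shannon entropy in bits, written independently of the package internals.
oracle_entropy <- function(y) {
  f <- table(y) / length(y)
  f <- f[f > 0]
  -sum(f * log2(f))
}
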