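#' Permutational multivariate analysis of variance on a distance matrix
#'
#' Partitions the total sum of squared distances into among- and
#' within-group components (Anderson's distance-based formulation) and
#' assesses the pseudo-F statistic by permuting group labels. When the
#' number of distinct label assignments is no larger than `n_permutations`
#' the null distribution is enumerated exhaustively (p = proportion of
#' assignments, observed included, with `F >= F_obs`); otherwise
#' `n_permutations` random permutations are drawn and
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_permutations)`.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param groups Group labels, either in the order of `labels(d)` or a named
#'   vector keyed by sample id. At least two groups with two samples each.
#' @param n_permutations Number of permutations (default 999, minimum 99).
#' @param seed Integer seed controlling the sampled permutations.
#' @return An object of class `permanova_result`: list with `pseudo_F`,
#'   `p_value`, `n_permutations` (effective count), `method`
#'   (`"exhaustive"` or `"sampled"`), `ss` (tibble of sums of squares and
#'   degrees of freedom) and `degenerate` (all distances zero).
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1) {
  dm <- as_distance_matrix(d)
  n <- nrow(dm)
  if (!is.null(names(groups))) {
    missing <- setdiff(rownames(dm), names(groups))
    if (length(missing) > 0) {
      abort(paste0("groups missing for sample(s): ",
                   paste(missing, collapse = ", ")))
    }
    groups <- groups[rownames(dm)]
  }
  g <- factor(unname(groups))
  if (length(g) != n) abort("`groups` length must match the distance matrix.")
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least two groups.")
  if (any(sizes < 2)) {
    abort(paste0("group(s) with fewer than 2 samples: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  if (n_permutations < 99) abort("n_permutations must be >= 99.")
  d2 <- dm^2
  a <- length(sizes)

  ss_total <- sum(d2) / (2 * n)
  f_stat <- function(gi) {
    ss_w <- 0
    for (lev in levels(g)) {
      idx <- which(gi == lev)
      ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ss_a <- ss_total - ss_w
    (ss_a / (a - 1)) / (ss_w / (n - a))
  }

  if (ss_total == 0) {
    return(structure(list(
      pseudo_F = NA_real_, p_value = 1, n_permutations = 0L,
      method = "degenerate",
      ss = tibble(term = c("among", "within", "total"),
                  ss = c(0, 0, 0), df = c(a - 1, n - a, n - 1)),
      degenerate = TRUE
    ), class = "permanova_result"))
  }

  f_obs <- f_stat(g)
  n_distinct <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))

  out <- with_seed(as.integer(seed), {
    if (is.finite(n_distinct) && n_distinct <= n_permutations) {
      assignments <- enumerate_assignments(as.vector(sizes), levels(g), n)
      f_perm <- vapply(assignments, f_stat, numeric(1))
      list(p = mean(f_perm >= f_obs - 1e-12),
           n_eff = length(assignments) - 1L, method = "exhaustive")
    } else {
      exceed <- 0L
      for (b in seq_len(n_permutations)) {
        if (f_stat(sample(g)) >= f_obs - 1e-12) exceed <- exceed + 1L
      }
      list(p = (1 + exceed) / (1 + n_permutations),
           n_eff = as.integer(n_permutations), method = "sampled")
    }
  })

  ss_w_obs <- local({
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  })
  structure(list(
    pseudo_F = f_obs, p_value = out$p, n_permutations = out$n_eff,
    method = out$method,
    ss = tibble(term = c("among", "within", "total"),
                ss = c(ss_total - ss_w_obs, ss_w_obs, ss_total),
                df = c(a - 1, n - a, n - 1)),
    degenerate = FALSE
  ), class = "permanova_result")
}

# All distinct assignments of n positions to groups with the given sizes.
# Only called when the count is small.
enumerate_assignments <- function(sizes, levels, n) {
  res <- list()
  recurse <- function(remaining, assignment, k) {
    if (k == length(sizes)) {
      assignment[remaining] <- levels[k]
      res[[length(res) + 1]] <<- factor(assignment, levels = levels)
      return(invisible())
    }
    picks <- combn(remaining, sizes[k], simplify = FALSE)
    for (p in picks) {
      a2 <- assignment
      a2[p] <- levels[k]
      recurse(setdiff(remaining, p), a2, k + 1)
    }
  }
  recurse(seq_len(n), character(n), 1)
  res
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova> pseudo-F = %.4g, p = %.4g (%s, %d permutations)\n",
              x$pseudo_F, x$p_value, x$method, x$n_permutations))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.permanova_result <- function(x, ...) x$ss

#' @exportS3Method generics::glance
glance.permanova_result <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, p_value = x$p_value,
         n_permutations = x$n_permutations, method = x$method)
}
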