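#' Information gain of a continuous feature about class labels
#'
#' Computes `IG = H(labels) - H(labels | binned feature)` in bits, after
#' supervised discretization of the feature by the Fayyad-Irani recursive
#' minimum-description-length (MDL) procedure (the discretization used by
#' WEKA's entropy-based attribute ranker). If the MDL criterion accepts no
#' split, the feature carries no usable information and the gain is 0.
#'
#' @param x Numeric feature values, one per sample.
#' @param y Class labels (coerced to factor).
#' @return Non-negative information gain in bits.
#' @examples
#' info_gain(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
#' @export
info_gain <- function(x, y) {
  x <- as.double(x)
  y <- factor(y)
  if (length(x) != length(y)) abort("`x` and `y` lengths differ.")
  if (length(x) < 2) abort("need at least 2 samples.")
  if (nlevels(droplevels(y)) < 2) {
    warn("constant labels: information gain is 0.")
    return(0)
  }
  cuts <- mdl_cuts(x, y)
  if (length(cuts) == 0) return(0)
  bins <- findInterval(x, sort(cuts))
  h_cond <- 0
  for (b in unique(bins)) {
    idx <- bins == b
    h_cond <- h_cond + mean(idx) * entropy_bits(y[idx])
  }
  max(entropy_bits(y) - h_cond, 0)
}

# Fayyad-Irani MDL cut points for a single continuous feature.
mdl_cuts <- function(x, y) {
  ord <- order(x)
  mdl_recurse(x[ord], y[ord])
}

mdl_recurse <- function(xs, ys) {
  n <- length(xs)
  if (n < 2) return(numeric(0))
  distinct <- which(diff(xs) > 0)
  if (length(distinct) == 0) return(numeric(0))
  ent_s <- entropy_bits(ys)
  k <- nlevels(droplevels(factor(ys)))

  best <- NULL
  best_e <- Inf
  for (i in distinct) {
    left <- ys[seq_len(i)]
    right <- ys[(i + 1):n]
    e <- (i / n) * entropy_bits(left) + ((n - i) / n) * entropy_bits(right)
    if (e < best_e) {
      best_e <- e
      best <- i
    }
  }
  gain <- ent_s - best_e
  left <- ys[seq_len(best)]
  right <- ys[(best + 1):n]
  k1 <- nlevels(droplevels(factor(left)))
  k2 <- nlevels(droplevels(factor(right)))
  delta <- log2(3^k - 2) -
    (k * ent_s - k1 * entropy_bits(left) - k2 * entropy_bits(right))
  if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  cut <- (xs[best] + xs[best + 1]) / 2
  c(mdl_recurse(xs[seq_len(best)], left),
    cut,
    mdl_recurse(xs[(best + 1):n], right))
}

#' Rank features by combined information gain and differential-abundance p
#'
#' Averages each feature's rank by descending information gain with its rank
#' by ascending p-value (average-rank method for ties); features are ordered
#' best-first by the combined rank, ties broken by feature id.
#'
#' @param info_gains Named numeric vector of information gains (bits).
#' @param p_values Named numeric vector of p-values over the same features;
#'   a feature missing here is assigned the worst p-rank with a warning.
#' @return A tibble ordered best-first: `feature`, `info_gain`, `p_value`,
#'   `ig_rank`, `p_rank`, `combined_rank`.
#' @export
rank_features <- function(info_gains, p_values) {
  feats <- names(info_gains)
  if (is.null(feats)) abort("`info_gains` must be named by feature.")
  p <- p_values[feats]
  names(p) <- feats
  if (anyNA(p)) {
    warn(sprintf("%d feature(s) lack a p-value; assigned the worst p-rank.",
                 sum(is.na(p))))
    p[is.na(p)] <- Inf
  }
  ig_rank <- rank(-info_gains, ties.method = "average")
  p_rank <- rank(p, ties.method = "average")
  out <- tibble(
    feature = feats,
    info_gain = unname(info_gains),
    p_value = unname(ifelse(is.infinite(p), NA_real_, p)),
    ig_rank = unname(ig_rank),
    p_rank = unname(p_rank),
    combined_rank = unname((ig_rank + p_rank) / 2)
  )
  arrange(out, .data$combined_rank, .data$feature)
}
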