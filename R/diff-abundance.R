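#' Per-OTU negative-binomial differential abundance between lines
#'
#' Fits, for every OTU, a negative-binomial generalized linear model
#' (log link) of counts on line with a library-size offset built from
#' trimmed-mean-of-M-values (TMM) normalization, and tests the line term by
#' likelihood ratio against the intercept-only model (1 df chi-square, with
#' the dispersion estimated under the full model and held fixed for the
#' comparison). P-values are corrected by Benjamini-Hochberg (FDR) and
#' Bonferroni over the tested OTU set.
#'
#' OTUs with zero counts in every sample cannot be tested and are dropped
#' with a warning. The table should already be low-count filtered (see
#' [filter_low_count()]).
#'
#' @param table An OTU tibble with at least two samples per line.
#' @param alpha Significance level for the flag columns (default 0.05).
#' @return A tibble with one row per tested OTU: `otu_id`, `log2_fc`
#'   (HAS over LAS), `p_value`, `fdr_p`, `bonferroni_p`, `sig_p`,
#'   `sig_fdr`.
#' @examples
#' sim <- simulate_otu_table(sim_config(n_otus = 40, n_genes = 100, seed = 1))
#' res <- diff_abundance(filter_low_count(sim$table))
#' @export
diff_abundance <- function(table, alpha = 0.05) {
  check_otu_table(table)
  line <- factor(table$line, levels = c("LAS", "HAS"))
  if (any(table(line) < 2)) abort("need at least 2 samples per line.")
  m <- otu_counts(table)

  zero <- colSums(m) == 0
  if (any(zero)) {
    warn(sprintf("excluding %d OTU(s) with all-zero counts.", sum(zero)))
    m <- m[, !zero, drop = FALSE]
  }
  if (ncol(m) == 0) abort("no testable OTUs.")

  # TMM normalization factors on the OTUs-by-samples orientation.
  nf <- edgeR::calcNormFactors(t(m))
  off <- log(rowSums(m) * nf)

  fit_one <- function(y) {
    res <- tryCatch({
      full <- suppressWarnings(
        MASS::glm.nb(y ~ line + offset(off),
                     control = stats::glm.control(maxit = 50))
      )
      theta <- full$theta
      list(theta = theta, coef = unname(stats::coef(full)["lineHAS"]))
    }, error = function(e) NULL)
    if (is.null(res)) {
      # near-Poisson or separated counts: moment dispersion, floored
      mu <- pmax(mean(y), 1e-8)
      phi <- max((var(y) - mu) / mu^2, 1e-4)
      res <- list(theta = 1 / phi, coef = NA_real_)
    }
    fam <- MASS::negative.binomial(res$theta)
    full2 <- suppressWarnings(stats::glm(y ~ line + offset(off), family = fam))
    null2 <- suppressWarnings(stats::glm(y ~ 1 + offset(off), family = fam))
    lrt <- max(null2$deviance - full2$deviance, 0)
    coefficient <- res$coef
    if (is.na(coefficient)) {
      coefficient <- unname(stats::coef(full2)["lineHAS"])
    }
    c(lfc = coefficient / log(2), p = pchisq(lrt, df = 1, lower.tail = FALSE))
  }

  fits <- apply(m, 2, fit_one)
  p <- unname(fits["p", ])
  tibble(
    otu_id = colnames(m),
    log2_fc = unname(fits["lfc", ]),
    p_value = p,
    fdr_p = p.adjust(p, method = "BH"),
    bonferroni_p = p.adjust(p, method = "bonferroni"),
    sig_p = p <= alpha,
    sig_fdr = p.adjust(p, method = "BH") <= alpha
  )
}
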