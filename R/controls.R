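#' Randomly reassign sample labels (negative-control permutation)
#'
#' Draws a uniformly random non-identity permutation of the sample indices,
#' so every label ends up attached to a different sample arrangement while
#' the label multiset is preserved exactly; features are untouched. Applying
#' the inverse permutation recovers the original pairing.
#'
#' @param labels Vector of sample labels.
#' @param seed Integer seed.
#' @return A list with `labels` (permuted) and `permutation` (the index
#'   vector such that `labels[permutation]` is the returned labelling).
#' @export
permute_labels <- function(labels, seed = 1) {
  n <- length(labels)
  if (n < 3) abort("need at least 3 samples to permute.")
  perm <- with_seed(as.integer(seed), {
    repeat {
      p <- sample(n)
      if (!identical(p, seq_len(n))) break
    }
    p
  })
  list(labels = labels[perm], permutation = perm)
}

#' Label-permutation negative control for the classifier ensemble
#'
#' Re-runs the full three-classifier / two-validation ensemble on datasets
#' whose labels have been randomly reassigned to other samples
#' (disassociating classifier from attributes), and summarizes how close the
#' resulting accuracies sit to the chance level. Chance is the empirical
#' majority-class frequency (0.5 for balanced two-class labels, ~1/3 for
#' balanced three-class labels), which also covers imbalanced
#' discretizations. Control seeds are derived so they never coincide with
#' the main-analysis seed.
#'
#' @inheritParams evaluate_ensemble
#' @param n_randomizations Number of permuted datasets (default 10).
#' @param seed Seed of the *main* analysis; controls derive their own seeds
#'   from it.
#' @return Object of class `control_result`: list with `runs` (tibble
#'   `run`, `average_accuracy`), `grand_mean`, `chance_level`, `gap`
#'   (`grand_mean - chance_level`) and `mc_se` (Monte-Carlo standard error
#'   of the grand mean).
#' @export
run_control <- function(data, label_col = "line", features = NULL,
                        n_randomizations = 10, config = ml_config(),
                        seed = 1, strata = NULL) {
  stopifnot(n_randomizations >= 1)
  y <- data[[label_col]]
  accs <- vapply(seq_len(n_randomizations), function(r) {
    perm_seed <- derive_seed(seed, paste0("control_perm_", r))
    eval_seed <- derive_seed(seed, paste0("control_eval_", r))
    if (identical(eval_seed, as.integer(seed))) eval_seed <- eval_seed + 1L
    perm <- permute_labels(y, seed = perm_seed)
    d <- data
    d[[label_col]] <- perm$labels
    st <- if (is.null(strata)) NULL else strata[perm$permutation]
    evaluate_ensemble(d, label_col = label_col, features = features,
                      config = config, seed = eval_seed,
                      strata = st)$average_accuracy
  }, numeric(1))
  chance <- max(table(y)) / length(y)
  structure(list(
    runs = tibble(run = seq_len(n_randomizations), average_accuracy = accs),
    grand_mean = mean(accs),
    chance_level = unname(chance),
    gap = mean(accs) - unname(chance),
    mc_se = if (n_randomizations > 1) {
      sd(accs) / sqrt(n_randomizations)
    } else {
      NA_real_
    }
  ), class = "control_result")
}

#' @export
print.control_result <- function(x, ...) {
  cat(sprintf(
    "<control_result> grand mean %.3f vs chance %.3f (gap %+.3f, MC se %.3f, n=%d)\n",
    x$grand_mean, x$chance_level, x$gap, x$mc_se, nrow(x$runs)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.control_result <- function(x, ...) x$runs

#' @exportS3Method generics::glance
glance.control_result <- function(x, ...) {
  tibble(n_randomizations = nrow(x$runs), grand_mean = x$grand_mean,
         chance_level = x$chance_level, gap = x$gap, mc_se = x$mc_se)
}

#' @param object A `control_result`.
#' @param ... Unused.
#' @rdname run_control
#' @exportS3Method ggplot2::autoplot
autoplot.control_result <- function(object, ...) {
  ggplot(object$runs, aes(.data$run, .data$average_accuracy)) +
    geom_col(fill = "grey70") +
    geom_hline(yintercept = object$chance_level, linetype = 2,
               colour = "red") +
    labs(x = "Randomization", y = "Ensemble average accuracy") +
    theme_minimal()
}
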