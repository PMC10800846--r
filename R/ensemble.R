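#' Machine-learning settings for the classifier ensemble
#'
#' Settings for the three-classifier / two-validation ensemble: a
#' linear-kernel support-vector classifier, a single-hidden-layer perceptron
#' and a CART decision tree, each validated by one stratified percent split
#' (66/34 by default, test size floored per class) and by stratified K-fold
#' hold-out (K = 6 by default, the number of biological replicates per line
#' and tissue).
#'
#' The perceptron's hidden layer follows the `(p + k)/2` sizing convention
#' for narrow feature sets but is capped so the total weight count stays
#' near `max_weights` (default 600); the quasi-Newton optimizer behind [nnet::nnet()]
#' scales quadratically in the number of weights, and with a dozen training
#' samples additional units add cost, not fit.
#'
#' @param classifiers Subset of `c("svm", "neural_net", "decision_tree")`.
#' @param split_fraction Training fraction of the percent split (default
#'   0.66).
#' @param k_folds Number of stratified hold-out folds (default 6).
#' @param nnet_maxit,nnet_decay,max_weights Perceptron fitting controls.
#' @param removal_fraction Fraction of worst-ranked features dropped per
#'   reduction iteration (default 0.2, at least one feature).
#' @param floor Smallest feature-set size the reduction descends to
#'   (default 5).
#' @param accuracy_threshold Per-OTU accuracy needed to stay in the final
#'   signature (default 0.75).
#' @return A list of class `ml_config`.
#' @export
ml_config <- function(classifiers = c("svm", "neural_net", "decision_tree"),
                      split_fraction = 0.66,
                      k_folds = 6,
                      nnet_maxit = 100,
                      nnet_decay = 0.1,
                      max_weights = 600,
                      removal_fraction = 0.2,
                      floor = 5,
                      accuracy_threshold = 0.75) {
  classifiers <- match.arg(classifiers,
                           c("svm", "neural_net", "decision_tree"),
                           several.ok = TRUE)
  stopifnot(split_fraction > 0, split_fraction < 1, k_folds >= 2,
            removal_fraction > 0, removal_fraction < 1, floor >= 1,
            accuracy_threshold >= 0, accuracy_threshold <= 1)
  structure(list(
    classifiers = classifiers,
    split_fraction = split_fraction,
    k_folds = as.integer(k_folds),
    nnet_maxit = as.integer(nnet_maxit),
    nnet_decay = nnet_decay,
    max_weights = as.integer(max_weights),
    removal_fraction = removal_fraction,
    floor = as.integer(floor),
    accuracy_threshold = accuracy_threshold
  ), class = "ml_config")
}

#' Evaluate the three-classifier / two-validation ensemble
#'
#' Runs every configured classifier under both validation schemes and
#' averages the six cells: the percent-split cell is the accuracy of one
#' stratified train/test split, the k-fold cell is the mean accuracy over
#' the K hold-out runs, and `average_accuracy` is the arithmetic mean of
#' all cells. Identical inputs and seed give identical results.
#'
#' @param data A tibble with one row per sample: the label column plus
#'   numeric feature columns (metadata columns `sample_id`, `line`,
#'   `tissue`, `replicate` are never used as features).
#' @param label_col Name of the class-label column (default `"line"`).
#' @param features Feature column names; default: all numeric non-metadata
#'   columns.
#' @param config An [ml_config()].
#' @param seed Integer seed controlling partitions and perceptron
#'   initialization.
#' @param strata Optional stratification labels for partition construction
#'   (defaults to the class labels themselves); rare-class handling in
#'   stage two passes merged strata here.
#' @return An object of class `ensemble_result`: list with `cells` (tibble
#'   `classifier`, `validation`, `accuracy`) and `average_accuracy`.
#' @examples
#' d <- tibble::tibble(line = rep(c("HAS", "LAS"), each = 6),
#'                     f1 = rep(c(0, 5), each = 6) + stats::rnorm(12, 0, 0.1))
#' evaluate_ensemble(d, config = ml_config(), seed = 1)
#' @export
evaluate_ensemble <- function(data, label_col = "line", features = NULL,
                              config = ml_config(), seed = 1,
                              strata = NULL) {
  stopifnot(is.data.frame(data), label_col %in% names(data))
  y <- droplevels(factor(data[[label_col]]))
  if (nlevels(y) < 2) abort("need at least 2 classes present.")
  if (is.null(features)) {
    numeric_cols <- names(data)[vapply(data, is.numeric, logical(1))]
    features <- setdiff(numeric_cols, c(META_COLS, label_col))
  }
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    abort(paste0("feature column(s) not in `data`: ",
                 paste(missing, collapse = ", ")))
  }
  x <- as.matrix(data[, features, drop = FALSE])
  storage.mode(x) <- "double"
  strata <- factor(strata %||% y)

  cells <- with_seed(as.integer(seed), {
    part <- draw_partitions(strata, y, config)
    grid <- tidyr::expand_grid(classifier = config$classifiers,
                               validation = c("percent_split",
                                              "kfold_holdout"))
    grid$accuracy <- NA_real_
    for (r in seq_len(nrow(grid))) {
      cls <- grid$classifier[r]
      if (grid$validation[r] == "percent_split") {
        acc <- run_holdout(cls, x, y, train = !part$test, config)
      } else {
        fold_acc <- vapply(seq_len(config$k_folds), function(f) {
          if (!any(part$folds == f)) return(NA_real_)
          run_holdout(cls, x, y, train = part$folds != f, config)
        }, numeric(1))
        acc <- mean(fold_acc, na.rm = TRUE)
      }
      grid$accuracy[r] <- acc
    }
    grid
  })

  structure(list(
    cells = cells,
    average_accuracy = mean(cells$accuracy, na.rm = TRUE),
    seed = as.integer(seed)
  ), class = "ensemble_result")
}

# Draw the stratified percent-split and fold assignments; re-draw (up to 10
# times) if some training partition would contain fewer than two classes.
draw_partitions <- function(strata, y, config) {
  for (attempt in 1:10) {
    test <- logical(length(y))
    for (lev in levels(strata)) {
      idx <- which(strata == lev)
      n_test <- floor(length(idx) * (1 - config$split_fraction))
      if (n_test > 0) test[sample(idx, n_test)] <- TRUE
    }
    if (!any(test)) test[sample(length(y), 1)] <- TRUE

    folds <- integer(length(y))
    for (lev in levels(strata)) {
      idx <- sample(which(strata == lev))
      folds[idx] <- ((seq_along(idx) - 1) %% config$k_folds) + 1
    }

    ok <- nlevels(droplevels(y[!test])) >= 2 &&
      all(vapply(seq_len(config$k_folds), function(f) {
        !any(folds == f) || nlevels(droplevels(y[folds != f])) >= 2
      }, logical(1)))
    if (ok) return(list(test = test, folds = folds))
    inform("partition left a training set with one class; redrawing.")
  }
  list(test = test, folds = folds)
}

run_holdout <- function(classifier, x, y, train, config) {
  if (all(train) || !any(train)) return(NA_real_)
  pred <- fit_predict(classifier,
                      x[train, , drop = FALSE], y[train],
                      x[!train, , drop = FALSE], config)
  mean(as.character(pred) == as.character(y[!train]))
}

fit_predict <- function(classifier, x_train, y_train, x_test, config) {
  y_train <- droplevels(y_train)
  majority <- names(which.max(table(y_train)))
  if (nlevels(y_train) < 2) {
    return(factor(rep(majority, nrow(x_test)), levels = levels(y_train)))
  }
  mu <- colMeans(x_train)
  sdev <- apply(x_train, 2, sd)
  sdev[sdev == 0] <- 1
  xs_train <- scale(x_train, center = mu, scale = sdev)
  xs_test <- scale(x_test, center = mu, scale = sdev)

  pred <- switch(classifier,
    svm = {
      fit <- e1071::svm(xs_train, y_train, kernel = "linear", scale = FALSE)
      as.character(predict(fit, xs_test))
    },
    neural_net = {
      p <- ncol(x_train)
      k <- nlevels(y_train)
      h <- max(1, min(ceiling((p + k) / 2),
                      floor(config$max_weights / (p + k + 1))))
      fit <- nnet::nnet(xs_train, nnet::class.ind(y_train), size = h,
                        softmax = TRUE, decay = config$nnet_decay,
                        maxit = config$nnet_maxit, MaxNWts = 1e6,
                        trace = FALSE)
      prob <- predict(fit, xs_test)
      levels(y_train)[max.col(prob, ties.method = "first")]
    },
    decision_tree = {
      df_train <- as.data.frame(xs_train)
      names(df_train) <- paste0("f", seq_len(ncol(xs_train)))
      df_train$.y <- y_train
      fit <- rpart::rpart(.y ~ ., data = df_train, method = "class",
                          control = rpart::rpart.control(
                            minsplit = 2, minbucket = 1, cp = 0,
                            maxdepth = 30, xval = 0))
      df_test <- as.data.frame(xs_test)
      names(df_test) <- paste0("f", seq_len(ncol(xs_test)))
      as.character(predict(fit, df_test, type = "class"))
    },
    abort(sprintf("unknown classifier '%s'.", classifier))
  )
  factor(pred, levels = levels(y_train))
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> average accuracy %.3f\n",
              x$average_accuracy))
  wide <- tidyr::pivot_wider(x$cells, names_from = "validation",
                             values_from = "accuracy")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ensemble_result <- function(x, ...) x$cells

#' @exportS3Method generics::glance
glance.ensemble_result <- function(x, ...) {
  tibble(average_accuracy = x$average_accuracy,
         n_cells = nrow(x$cells),
         n_missing_cells = sum(is.na(x$cells$accuracy)))
}
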