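#' Iterative dimensionality reduction toward a minimal microbial signature
#'
#' Starting from all ranked features, evaluates the classifier ensemble,
#' drops the worst-ranked fraction (default 20%, at least one feature),
#' re-evaluates, and repeats until the configured floor. The best set is the
#' one maximizing average accuracy, with the smallest set winning ties. The
#' same seed is reused at every iteration so fold assignments are comparable
#' across feature-set sizes.
#'
#' @param data A tibble of samples: label column plus one numeric column per
#'   feature (e.g. a single-tissue slice of an OTU tibble).
#' @param ranked A tibble from [rank_features()] (best-first order) covering
#'   the features to consider.
#' @param label_col Class-label column name (default `"line"`).
#' @param config An [ml_config()].
#' @param seed Integer seed.
#' @return An object of class `signature_result`: list with `iterations`
#'   (tibble `iteration`, `n_features`, `average_accuracy`, `features`
#'   list-column), `best_set` (character), and slots `per_otu` /
#'   `final_signature` filled by the pipeline after
#'   [per_feature_performance()] and [filter_signature()].
#' @export
reduce_features <- function(data, ranked, label_col = "line",
                            config = ml_config(), seed = 1) {
  stopifnot(is.data.frame(ranked), "feature" %in% names(ranked))
  feats <- ranked$feature
  missing <- setdiff(feats, names(data))
  if (length(missing) > 0) {
    abort(paste0("ranked feature(s) not in `data`: ",
                 paste(missing, collapse = ", ")))
  }
  current <- feats
  rows <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    res <- evaluate_ensemble(data, label_col = label_col,
                             features = current, config = config,
                             seed = seed)
    rows[[iter]] <- tibble(iteration = iter,
                           n_features = length(current),
                           average_accuracy = res$average_accuracy,
                           features = list(current))
    if (length(current) <= config$floor) break
    n_drop <- max(1L, ceiling(config$removal_fraction * length(current)))
    new_len <- max(config$floor, length(current) - n_drop)
    current <- head(current, new_len)
  }
  iterations <- bind_rows(rows)
  best_i <- with(iterations, {
    cand <- which(average_accuracy == max(average_accuracy))
    cand[which.min(n_features[cand])]
  })
  structure(list(
    iterations = iterations,
    best_set = iterations$features[[best_i]],
    best_accuracy = iterations$average_accuracy[best_i],
    per_otu = NULL,
    final_signature = NULL,
    seed = as.integer(seed)
  ), class = "signature_result")
}

#' Individual predictive performance of each candidate OTU
#'
#' Evaluates the full ensemble with each OTU as the sole attribute, reusing
#' the same seed (hence the same fold assignments) for every OTU so the
#' per-OTU accuracies are comparable.
#'
#' @inheritParams reduce_features
#' @param otus Character vector of feature columns to evaluate singly.
#' @return A tibble `otu_id`, `accuracy`, ordered as `otus`.
#' @export
per_feature_performance <- function(data, otus, label_col = "line",
                                    config = ml_config(), seed = 1) {
  missing <- setdiff(otus, names(data))
  if (length(missing) > 0) {
    abort(paste0("OTU column(s) not in `data`: ",
                 paste(missing, collapse = ", ")))
  }
  acc <- vapply(otus, function(o) {
    evaluate_ensemble(data, label_col = label_col, features = o,
                      config = config, seed = seed)$average_accuracy
  }, numeric(1))
  tibble(otu_id = otus, accuracy = unname(acc))
}

#' Apply the performance and line-exclusivity filters to candidate OTUs
#'
#' Retains the OTUs whose individual predictive accuracy meets the threshold
#' and which are present (count > 0) in at least one sample of each line;
#' OTUs exclusive to a single line are removed even when highly predictive,
#' since their predictiveness is mere presence/absence of the line itself.
#'
#' @param per_otu A tibble from [per_feature_performance()] (`otu_id`,
#'   `accuracy`) or a named accuracy vector.
#' @param table The OTU tibble over which line presence is judged.
#' @param threshold Minimum individual accuracy (default 0.75).
#' @return A tibble `otu_id`, `accuracy`, `present_has`, `present_las`,
#'   `retained`; the final signature is `otu_id[retained]`.
#' @export
filter_signature <- function(per_otu, table, threshold = 0.75) {
  if (!is.data.frame(per_otu)) {
    per_otu <- tibble(otu_id = names(per_otu), accuracy = unname(per_otu))
  }
  stopifnot(all(c("otu_id", "accuracy") %in% names(per_otu)),
            nrow(per_otu) > 0)
  pres <- presence_partition(table)
  out <- per_otu |>
    left_join(select(pres, "otu_id", "present_has", "present_las"),
              by = "otu_id") |>
    mutate(
      present_has = tidyr::replace_na(.data$present_has, FALSE),
      present_las = tidyr::replace_na(.data$present_las, FALSE),
      retained = .data$accuracy >= threshold &
        .data$present_has & .data$present_las
    )
  if (!any(out$retained)) {
    warn("no OTU survives the performance and exclusivity filters.")
  }
  out
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("<signature_result> %d iterations, best set of %d (avg acc %.3f)\n",
              nrow(x$iterations), length(x$best_set), x$best_accuracy))
  if (!is.null(x$final_signature)) {
    cat(sprintf("  final signature: %d OTU(s)\n", length(x$final_signature)))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.signature_result <- function(x, ...) {
  select(x$iterations, "iteration", "n_features", "average_accuracy")
}

#' @exportS3Method generics::glance
glance.signature_result <- function(x, ...) {
  tibble(n_iterations = nrow(x$iterations),
         best_n_features = length(x$best_set),
         best_average_accuracy = x$best_accuracy,
         final_signature_size = length(x$final_signature %||% character(0)))
}

#' @param object A `signature_result`.
#' @param ... Unused.
#' @rdname reduce_features
#' @exportS3Method ggplot2::autoplot
autoplot.signature_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(.data$n_features, .data$average_accuracy)) +
    geom_line(colour = "grey50") +
    geom_point() +
    scale_x_reverse() +
    labs(x = "Features retained", y = "Ensemble average accuracy") +
    theme_minimal()
}
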