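#' Rank genes by information gain about an OTU's abundance classes
#'
#' Stage two ranks by information gain alone (no differential-expression
#' p-value exists for an abundance-class contrast). Expression is used on
#' the log2(TPM + 1) scale.
#'
#' @param expr An expression tibble (`sample_id` plus gene columns, TPM).
#' @param classes An `abundance_classes` object over the same samples.
#' @return A tibble ordered best-first: `gene`, `info_gain`, `rank` (ties
#'   broken by gene id).
#' @export
rank_genes <- function(expr, classes) {
  stopifnot(inherits(classes, "abundance_classes"))
  if (classes$degenerate) {
    abort("degenerate abundance classes (single class); exclude this OTU.")
  }
  cl <- setNames(as.character(classes$classes$class),
                 classes$classes$sample_id)
  missing <- setdiff(expr$sample_id, names(cl))
  if (length(missing) > 0) {
    abort(paste0("samples without a class label: ",
                 paste(missing, collapse = ", ")))
  }
  y <- factor(cl[expr$sample_id])
  m <- log2(expr_values(expr) + 1)
  ig <- vapply(seq_len(ncol(m)), function(j) info_gain(m[, j], y), numeric(1))
  tibble(gene = colnames(m), info_gain = ig) |>
    arrange(desc(.data$info_gain), .data$gene) |>
    mutate(rank = dplyr::row_number())
}

#' Default gene-list size grid
#'
#' Sizes spanning the 35-500 range of reported optimal gene-list sizes,
#' truncated to the number of available genes; if none fits, falls back to
#' powers of two below the gene count.
#'
#' @param n_genes Number of genes available.
#' @return Increasing integer vector of candidate list sizes.
#' @export
default_size_grid <- function(n_genes) {
  grid <- c(35L, 50L, 83L, 100L, 228L, 312L, 339L, 349L, 500L)
  grid <- grid[grid <= n_genes]
  if (length(grid) == 0) {
    grid <- 2L^(seq_len(max(1, floor(log2(n_genes)))))
    grid <- unique(pmin(grid, n_genes))
  }
  grid
}

#' Optimize the gene-list size predicting an OTU's abundance class
#'
#' For each candidate size `s`, evaluates the three-classifier /
#' two-validation ensemble on the top-`s` genes by information gain, with
#' the abundance class as the target; the best size maximizes average
#' accuracy (smallest on ties). Classes too rare to stratify (< 2 samples)
#' are merged into their nearest ordinal neighbour *for fold construction
#' only* (the merge is recorded), since with a dozen samples and up to four
#' classes strictly stratified folds are often impossible.
#'
#' @param expr Expression tibble (TPM).
#' @param classes An `abundance_classes` object for the target OTU.
#' @param ranked Output of [rank_genes()]; computed if `NULL`.
#' @param size_grid Candidate sizes (default [default_size_grid()]).
#' @param config An [ml_config()].
#' @param seed Integer seed.
#' @return Object of class `gene_list_result`: list with `otu_id`, `grid`
#'   (tibble `size`, `average_accuracy`), `best_size`, `best_genes`
#'   (ordered), `best_accuracy`, `merged_classes` (logical) and `ranked`.
#' @export
optimize_gene_list <- function(expr, classes, ranked = NULL,
                               size_grid = NULL, config = ml_config(),
                               seed = 1) {
  stopifnot(inherits(classes, "abundance_classes"))
  if (classes$degenerate) {
    abort("degenerate abundance classes (single class); exclude this OTU.")
  }
  ranked <- ranked %||% rank_genes(expr, classes)
  n_genes <- nrow(ranked)
  size_grid <- sort(unique(as.integer(size_grid %||%
                                        default_size_grid(n_genes))))
  if (length(size_grid) == 0 || any(size_grid < 1) ||
      any(size_grid > n_genes)) {
    abort("`size_grid` must be non-empty with sizes in [1, n_genes].")
  }

  cl <- setNames(as.character(classes$classes$class),
                 classes$classes$sample_id)
  y <- factor(cl[expr$sample_id])
  strata <- merge_rare_classes(y)
  dat <- expr
  gene_cols <- setdiff(names(expr), "sample_id")
  dat[gene_cols] <- log2(dat[gene_cols] + 1)
  dat$.class <- y

  grid <- tibble(size = size_grid, average_accuracy = NA_real_)
  for (i in seq_along(size_grid)) {
    top <- ranked$gene[seq_len(size_grid[i])]
    res <- evaluate_ensemble(dat, label_col = ".class", features = top,
                             config = config, seed = seed, strata = strata)
    grid$average_accuracy[i] <- res$average_accuracy
  }
  best_i <- local({
    cand <- which(grid$average_accuracy == max(grid$average_accuracy))
    cand[which.min(grid$size[cand])]
  })
  structure(list(
    otu_id = classes$otu_id,
    grid = grid,
    best_size = grid$size[best_i],
    best_genes = ranked$gene[seq_len(grid$size[best_i])],
    best_accuracy = grid$average_accuracy[best_i],
    merged_classes = !identical(levels(strata), levels(droplevels(y))),
    ranked = ranked
  ), class = "gene_list_result")
}

# Merge classes with fewer than 2 samples into the nearest ordinal
# neighbour (Absent -> Low; Medium -> larger of Low/High; chain upward),
# for stratification only.
merge_rare_classes <- function(y) {
  ladder <- intersect(c("Absent", "Low", "Medium", "High"), levels(y))
  strata <- factor(as.character(y), levels = ladder)
  repeat {
    sizes <- table(strata)
    rare <- names(sizes)[sizes > 0 & sizes < 2]
    if (length(rare) == 0 || length(sizes[sizes > 0]) <= 1) break
    lev <- rare[1]
    present <- names(sizes)[sizes > 0 & names(sizes) != lev]
    pos <- match(lev, ladder)
    target <- present[which.min(abs(match(present, ladder) - pos))]
    strata <- factor(ifelse(strata == lev, target, as.character(strata)),
                     levels = ladder)
  }
  droplevels(strata)
}

#' @export
print.gene_list_result <- function(x, ...) {
  cat(sprintf("<gene_list_result%s> best size %d, accuracy %.3f%s\n",
              if (is.null(x$otu_id)) "" else paste0(" ", x$otu_id),
              x$best_size, x$best_accuracy,
              if (x$merged_classes) " [rare classes merged for folds]" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gene_list_result <- function(x, ...) x$grid

#' @exportS3Method generics::glance
glance.gene_list_result <- function(x, ...) {
  tibble(otu_id = x$otu_id %||% NA_character_,
         best_size = x$best_size,
         best_accuracy = x$best_accuracy,
         merged_classes = x$merged_classes)
}

#' @param object A `gene_list_result`.
#' @param ... Unused.
#' @rdname optimize_gene_list
#' @exportS3Method ggplot2::autoplot
autoplot.gene_list_result <- function(object, ...) {
  ggplot(object$grid, aes(.data$size, .data$average_accuracy)) +
    geom_line(colour = "grey50") +
    geom_point() +
    labs(x = "Gene-list size", y = "Ensemble average accuracy") +
    theme_minimal()
}

#' Export per-OTU ranked gene lists and a summary table
#'
#' Writes one plain-text ranked gene list per OTU (suitable for external
#' pathway-enrichment tools) and a summary TSV with one row per OTU: the
#' OTU's line-prediction accuracy (if supplied), its best stage-two
#' accuracy and gene-list size, and a status flag. Degenerate OTUs (entries
#' that are `NULL`) get a summary row but no list file.
#'
#' @param results Named list (by OTU id) of `gene_list_result` objects;
#'   `NULL` entries mark OTUs whose discretization was degenerate.
#' @param dir Output directory (created if needed).
#' @param line_accuracy Optional named numeric vector of stage-one per-OTU
#'   accuracies.
#' @return Invisibly, the summary tibble (also written to
#'   `file.path(dir, "gene_list_summary.tsv")`).
#' @export
export_gene_lists <- function(results, dir, line_accuracy = NULL) {
  stopifnot(length(results) > 0, !is.null(names(results)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- imap(results, function(res, otu) {
    if (is.null(res)) {
      return(tibble(otu_id = otu,
                    line_prediction_accuracy =
                      unname(line_accuracy[otu]) %||% NA_real_,
                    best_accuracy = NA_real_, best_size = NA_integer_,
                    status = "degenerate"))
    }
    path <- file.path(dir, paste0("genes_", otu, ".txt"))
    tryCatch(writeLines(res$best_genes, path),
             error = function(e) {
               abort(sprintf("failed writing '%s': %s", path,
                             conditionMessage(e)))
             })
    tibble(otu_id = otu,
           line_prediction_accuracy =
             unname(line_accuracy[otu]) %||% NA_real_,
           best_accuracy = res$best_accuracy,
           best_size = as.integer(res$best_size),
           status = "ok")
  })
  summary <- bind_rows(rows)
  readr::write_tsv(summary, file.path(dir, "gene_list_summary.tsv"))
  invisible(summary)
}
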