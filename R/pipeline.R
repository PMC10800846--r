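#' Configuration for an end-to-end pipeline run
#'
#' Either a synthetic-study configuration (`sim`) or a set of input paths
#' (`paths`) must be supplied, never both. Defaults follow the study design
#' the pipeline emulates: a 10-count low-count filter, a jejunum stage-one
#' sample universe, 66/34 percent split, K = 6 folds, 20% removal per
#' reduction iteration, a 75% per-OTU accuracy threshold and ten
#' negative-control randomizations.
#'
#' @param sim A [sim_config()], or `NULL` when `paths` is given.
#' @param paths Named list with `counts`, `meta`, `tree` and optionally
#'   `expression`, or `NULL` when `sim` is given.
#' @param min_total Low-count filter threshold (default 10).
#' @param stage1_tissue Tissue slice used as the stage-one (and stage-two)
#'   sample universe (default `"jejunum"`); `NULL` uses all samples.
#' @param ml An [ml_config()].
#' @param signature_size Target size of the stage-one candidate signature:
#'   per-OTU evaluation runs on the reduction iteration with the smallest
#'   feature count at or above this value (default 20, the top-OTU set size
#'   the workflow narrows before the individual-performance filters);
#'   `NULL` uses the accuracy-maximizing best set instead.
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param n_randomizations Negative-control randomizations (default 10).
#' @param size_grid Stage-two gene-list sizes (default
#'   [default_size_grid()]).
#' @param seed Master seed; every stage derives its own child seed from it,
#'   so stages are reproducible independently of execution order.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), paths = NULL, min_total = 10,
                       stage1_tissue = "jejunum", ml = ml_config(),
                       signature_size = 20, n_permutations = 999,
                       n_randomizations = 10, size_grid = NULL, seed = 1) {
  if (is.null(sim) == is.null(paths)) {
    abort("supply exactly one of `sim` or `paths`.")
  }
  if (!is.null(paths)) {
    stopifnot(all(c("counts", "meta", "tree") %in% names(paths)))
  }
  structure(list(
    sim = sim, paths = paths, min_total = min_total,
    stage1_tissue = stage1_tissue, ml = ml,
    signature_size = if (!is.null(signature_size)) {
      as.integer(signature_size)
    },
    n_permutations = as.integer(n_permutations),
    n_randomizations = as.integer(n_randomizations),
    size_grid = size_grid, seed = as.integer(seed)
  ), class = "run_config")
}

#' Stage-one candidate set taken forward to per-OTU evaluation
#'
#' The reduction iteration with the smallest feature count at or above the
#' target size; with a `NULL` target, the accuracy-maximizing best set.
#'
#' @param sig A `signature_result`.
#' @param signature_size Target candidate size, or `NULL`.
#' @return Character vector of OTU ids.
#' @export
signature_candidate <- function(sig, signature_size = 20) {
  stopifnot(inherits(sig, "signature_result"))
  if (is.null(signature_size)) return(sig$best_set)
  it <- sig$iterations
  ok <- which(it$n_features >= signature_size)
  if (length(ok) == 0) return(it$features[[1]])
  it$features[[ok[which.min(it$n_features[ok])]]]
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (simulation or reading), low-count
#' filtering with diversity/ordination/PERMANOVA, per-OTU differential
#' abundance, stage-one signature discovery on the configured tissue slice,
#' abundance discretization of the final signature, stage-two gene-list
#' optimization per signature OTU, and label-permutation negative controls.
#' All artifacts are written under `dir` as TSV/JSON plus a manifest;
#' rerunning with the same configuration reproduces identical result files.
#'
#' @param config A [run_config()].
#' @param dir Output directory (created; default a fresh temporary
#'   directory).
#' @return Invisibly, a list with all in-memory stage results and `dir`.
#' @export
run_pipeline <- function(config, dir = tempfile("linesig_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  jw <- function(x, path) {
    jsonlite::write_json(x, file.path(dir, path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }

  # -- stage 1: data --------------------------------------------------------
  truth <- NULL
  acquired <- stage("data", {
    if (!is.null(config$sim)) {
      study <- simulate_study(config$sim)
      truth <- study$truth
      write_otu_table(study$table, file.path(dir, "counts.tsv"),
                      file.path(dir, "metadata.tsv"))
      ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
      write_expression(study$expression, file.path(dir, "expression.tsv"))
      jw(truth, "ground_truth.json")
      study
    } else {
      read_inputs(config$paths$counts, config$paths$meta,
                  config$paths$tree, config$paths$expression)
    }
  })
  table <- acquired$table
  tree <- acquired$tree
  expression <- acquired$expression

  # -- stage 2: filtering + diversity --------------------------------------
  diversity <- stage("diversity", {
    filtered <- filter_low_count(table, min_total = config$min_total)
    part <- presence_partition(filtered)
    alpha <- observed_otus(filtered, "line_tissue")
    d <- weighted_unifrac(filtered, tree)
    ord <- ordinate_pcoa(d, n_axes = 2)
    perm_line <- permanova(d, setNames(filtered$line, filtered$sample_id),
                           n_permutations = config$n_permutations,
                           seed = derive_seed(config$seed, "permanova_line"))
    perm_tissue <- if (length(unique(filtered$tissue)) > 1) {
      permanova(d, setNames(filtered$tissue, filtered$sample_id),
                n_permutations = config$n_permutations,
                seed = derive_seed(config$seed, "permanova_tissue"))
    }
    readr::write_tsv(part, file.path(dir, "presence_partition.tsv"))
    readr::write_tsv(alpha, file.path(dir, "alpha_diversity.tsv"))
    dm <- as.matrix(d)
    readr::write_tsv(bind_cols(tibble(sample_id = rownames(dm)),
                               as_tibble(dm)),
                     file.path(dir, "unifrac.tsv"))
    readr::write_tsv(ord$coordinates, file.path(dir, "pcoa.tsv"))
    jw(list(line = as.list(glance(perm_line)),
            tissue = if (!is.null(perm_tissue)) {
              as.list(glance(perm_tissue))
            }), "permanova.json")
    list(filtered = filtered, partition = part, alpha = alpha,
         unifrac = d, pcoa = ord, permanova_line = perm_line,
         permanova_tissue = perm_tissue)
  })
  filtered <- diversity$filtered

  # -- stage 3: differential abundance -------------------------------------
  da <- stage("diff_abundance", {
    res <- diff_abundance(filtered)
    readr::write_tsv(res, file.path(dir, "diff_abundance.tsv"))
    res
  })

  # -- stage 4: stage-one signature ----------------------------------------
  signature <- stage("signature", {
    universe <- filtered
    if (!is.null(config$stage1_tissue)) {
      if (!config$stage1_tissue %in% filtered$tissue) {
        abort(sprintf("stage1_tissue '%s' not present in the data.",
                      config$stage1_tissue))
      }
      universe <- filter(filtered, .data$tissue == config$stage1_tissue)
    }
    ids <- otu_ids(universe)
    y <- factor(universe$line)
    ig <- vapply(ids, function(o) {
      suppressWarnings(info_gain(universe[[o]], y))
    }, numeric(1))
    p <- setNames(da$p_value, da$otu_id)[ids]
    names(p) <- ids
    ranked <- suppressWarnings(rank_features(ig, p))
    sig <- reduce_features(universe, ranked, label_col = "line",
                           config = config$ml,
                           seed = derive_seed(config$seed, "stage1"))
    candidate <- signature_candidate(sig, config$signature_size)
    per_otu <- per_feature_performance(universe, candidate,
                                       label_col = "line",
                                       config = config$ml,
                                       seed = derive_seed(config$seed,
                                                          "stage1"))
    filt <- filter_signature(per_otu, universe,
                             threshold = config$ml$accuracy_threshold)
    sig$per_otu <- per_otu
    sig$final_signature <- filt$otu_id[filt$retained]
    readr::write_tsv(ranked, file.path(dir, "ranked_features.tsv"))
    jw(purrr::transpose(select(sig$iterations, -"features")),
       "signature_iterations.json")
    readr::write_tsv(filt, file.path(dir, "signature_filter.tsv"))
    list(universe = universe, ranked = ranked, result = sig,
         candidate = candidate, filter = filt)
  })
  final_sig <- signature$result$final_signature

  # -- stage 5: abundance classes ------------------------------------------
  classes <- stage("discretize", {
    if (length(final_sig) == 0) {
      list(grid = tibble(), details = list(), degenerate = character(0))
    } else {
      cg <- class_grid(signature$universe, final_sig)
      readr::write_tsv(cg$grid, file.path(dir, "class_grid.tsv"))
      jw(lapply(cg$details, function(d) {
        list(scheme = d$scheme, mean = d$mean,
             cutoffs = as.list(d$cutoffs), degenerate = d$degenerate)
      }), "class_thresholds.json")
      cg
    }
  })

  # -- stage 6: stage-two gene lists ---------------------------------------
  gene_lists <- stage("gene_lists", {
    stage2_otus <- setdiff(final_sig, classes$degenerate)
    if (is.null(expression) || length(stage2_otus) == 0) {
      list(results = list(), summary = tibble())
    } else {
      expr_universe <- expression[
        match(signature$universe$sample_id, expression$sample_id), ]
      results <- lapply(stage2_otus, function(o) {
        optimize_gene_list(expr_universe, classes$details[[o]],
                           size_grid = config$size_grid, config = config$ml,
                           seed = derive_seed(config$seed,
                                              paste0("stage2_", o)))
      })
      names(results) <- stage2_otus
      all_results <- setNames(vector("list", length(final_sig)), final_sig)
      all_results[stage2_otus] <- results
      line_acc <- setNames(signature$result$per_otu$accuracy,
                           signature$result$per_otu$otu_id)
      summary <- if (length(all_results) > 0) {
        export_gene_lists(all_results, file.path(dir, "gene_lists"),
                          line_accuracy = line_acc)
      } else {
        tibble()
      }
      jw(lapply(results, function(r) {
        list(otu_id = r$otu_id, best_size = r$best_size,
             best_accuracy = r$best_accuracy,
             grid = purrr::transpose(r$grid))
      }), "gene_list_grids.json")
      list(results = results, summary = summary)
    }
  })

  # -- stage 7: negative controls ------------------------------------------
  controls <- stage("controls", {
    line_features <- signature$result$best_set
    line_ctrl <- run_control(signature$universe, label_col = "line",
                             features = line_features,
                             n_randomizations = config$n_randomizations,
                             config = config$ml,
                             seed = derive_seed(config$seed, "control_line"))
    abundance_ctrls <- list()
    if (!is.null(expression) && length(gene_lists$results) > 0) {
      expr_universe <- expression[
        match(signature$universe$sample_id, expression$sample_id), ]
      gene_cols <- setdiff(names(expr_universe), "sample_id")
      expr_log <- expr_universe
      expr_log[gene_cols] <- log2(expr_log[gene_cols] + 1)
      for (o in names(gene_lists$results)) {
        res <- gene_lists$results[[o]]
        det <- classes$details[[o]]
        cl <- setNames(as.character(det$classes$class),
                       det$classes$sample_id)
        d <- expr_log
        d$.class <- factor(cl[d$sample_id])
        abundance_ctrls[[o]] <- run_control(
          d, label_col = ".class", features = res$best_genes,
          n_randomizations = config$n_randomizations, config = config$ml,
          seed = derive_seed(config$seed, paste0("control_", o)),
          strata = merge_rare_classes(d$.class))
      }
    }
    jw(c(list(line = as.list(glance(line_ctrl))),
         lapply(abundance_ctrls, function(x) as.list(glance(x)))),
       "controls.json")
    list(line = line_ctrl, abundance = abundance_ctrls)
  })

  # -- manifest + report ----------------------------------------------------
  manifest <- list(
    package = "linesig",
    version = as.character(utils::packageVersion("linesig")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = derive_seed(0, paste(deparse(config[setdiff(
      names(config), c("ml", "sim"))]), collapse = "")),
    min_total = config$min_total,
    stage1_tissue = config$stage1_tissue,
    synthetic = !is.null(config$sim)
  )
  jw(manifest, "manifest.json")

  results <- list(dir = dir, config = config, truth = truth, table = table,
                  tree = tree, expression = expression,
                  diversity = diversity, diff_abundance = da,
                  signature = signature, classes = classes,
                  gene_lists = gene_lists, controls = controls,
                  manifest = manifest)
  stage("report", render_report(dir))
  invisible(results)
}
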