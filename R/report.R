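#' Render the run report from a pipeline run directory
#'
#' Reads only the serialized artifacts of [run_pipeline()] (so a report can
#' be re-rendered without re-running any stage) and writes `report.md` and
#' `report.json` into the same directory. The report mirrors the study's
#' result surfaces: OTU totals and filtered count, the per-line presence
#' partition, observed-OTU alpha diversity, PCoA coordinates, the
#' differential-abundance table, the signature reduction trace, the
#' abundance-class grid, the per-OTU gene-list summary and the
#' negative-control gaps. Missing artifacts render as placeholders.
#'
#' @param dir A run directory produced by [run_pipeline()].
#' @return Invisibly, the report list (also written as JSON).
#' @export
render_report <- function(dir) {
  rd_tsv <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) readr::read_tsv(p, show_col_types = FALSE) else NULL
  }
  rd_json <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) jsonlite::read_json(p) else NULL
  }

  counts <- rd_tsv("counts.tsv")
  meta <- rd_tsv("metadata.tsv")
  part <- rd_tsv("presence_partition.tsv")
  alpha <- rd_tsv("alpha_diversity.tsv")
  pcoa <- rd_tsv("pcoa.tsv")
  permanova <- rd_json("permanova.json")
  da <- rd_tsv("diff_abundance.tsv")
  iters <- rd_json("signature_iterations.json")
  sig_filter <- rd_tsv("signature_filter.tsv")
  grid <- rd_tsv("class_grid.tsv")
  gl_summary <- rd_tsv(file.path("gene_lists", "gene_list_summary.tsv"))
  controls <- rd_json("controls.json")
  manifest <- rd_json("manifest.json")

  part_counts <- if (!is.null(part)) {
    as.list(table(factor(part$partition,
                         levels = c("HAS_only", "LAS_only", "both"))))
  }
  stage1_best <- if (!is.null(iters)) {
    max(vapply(iters, function(x) x$average_accuracy, numeric(1)))
  }
  line_chance <- if (!is.null(controls)) controls$line$chance_level
  stage2_best <- if (!is.null(gl_summary) && nrow(gl_summary) > 0) {
    suppressWarnings(max(gl_summary$best_accuracy, na.rm = TRUE))
  }

  report <- list(
    manifest = manifest %||% "missing",
    samples = if (!is.null(meta)) {
      list(n = nrow(meta),
           per_line = as.list(table(meta$line)),
           per_tissue = as.list(table(meta$tissue)))
    } else "missing",
    otus = list(
      total = if (!is.null(counts)) nrow(counts) else "missing",
      retained = if (!is.null(part)) nrow(part) else "missing"
    ),
    presence_partition = part_counts %||% "missing",
    alpha_diversity = if (!is.null(alpha)) {
      purrr::transpose(alpha)
    } else "missing",
    pcoa = if (!is.null(pcoa)) purrr::transpose(pcoa) else "missing",
    permanova = permanova %||% "missing",
    diff_abundance = if (!is.null(da)) {
      list(n_tested = nrow(da),
           n_sig_fdr = sum(da$sig_fdr),
           n_sig_p = sum(da$sig_p))
    } else "missing",
    signature = if (!is.null(iters)) {
      list(trace = iters,
           best_accuracy = stage1_best,
           final_signature = if (!is.null(sig_filter)) {
             sig_filter$otu_id[sig_filter$retained]
           } else list())
    } else "missing",
    class_grid = if (!is.null(grid)) purrr::transpose(grid) else "missing",
    gene_lists = if (!is.null(gl_summary)) {
      purrr::transpose(gl_summary)
    } else "missing",
    controls = controls %||% "missing",
    flags = list(
      stage1_within_chance_band =
        if (!is.null(stage1_best) && !is.null(controls$line)) {
          within_control_band(stage1_best, controls$line, floor = 0.10)
        } else NA,
      stage2_within_chance_band =
        if (!is.null(stage2_best) && is.finite(stage2_best) &&
            !is.null(controls) && length(controls) > 1) {
          ab <- controls[setdiff(names(controls), "line")]
          all(vapply(ab, function(ctrl) {
            within_control_band(stage2_best, ctrl, floor = 0.12)
          }, logical(1)))
        } else NA
    )
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(report_markdown(report), file.path(dir, "report.md"))
  invisible(report)
}

# An observed accuracy is "within the chance band" when it does not exceed
# the label-permutation control's grand mean by more than three standard
# deviations of the control runs (floored at `floor`): best-of-trace
# accuracies are selection-biased upward under the null, so the band is
# anchored on the permuted distribution, not on the nominal chance level.
within_control_band <- function(observed, ctrl, floor) {
  spread <- if (!is.null(ctrl$mc_se) && is.numeric(ctrl$mc_se) &&
                is.finite(ctrl$mc_se)) {
    3 * ctrl$mc_se * sqrt(ctrl$n_randomizations)
  } else {
    0
  }
  observed <= ctrl$grand_mean + max(floor, spread)
}

report_markdown <- function(report) {
  num <- function(x, d = 3) {
    if (is.null(x) || !is.numeric(x)) "n/a" else formatC(x, digits = d,
                                                         format = "fg")
  }
  sec <- function(title, body) c(paste0("## ", title), "", body, "")
  lines <- c("# Line-signature pipeline report", "")
  lines <- c(lines, sec("Inputs", c(
    paste0("- samples: ", num(report$samples$n %||% NULL, 6)),
    paste0("- OTUs total: ", num(report$otus$total, 6)),
    paste0("- OTUs after low-count filter: ", num(report$otus$retained, 6))
  )))
  if (is.list(report$presence_partition)) {
    pp <- report$presence_partition
    lines <- c(lines, sec("Presence partition", c(
      paste0("- HAS only: ", pp$HAS_only), paste0("- LAS only: ", pp$LAS_only),
      paste0("- both lines: ", pp$both)
    )))
  }
  if (is.list(report$diff_abundance)) {
    daz <- report$diff_abundance
    lines <- c(lines, sec("Differential abundance", c(
      paste0("- OTUs tested: ", daz$n_tested),
      paste0("- significant at FDR p <= 0.05: ", daz$n_sig_fdr),
      paste0("- significant at raw p <= 0.05: ", daz$n_sig_p)
    )))
  }
  if (is.list(report$permanova) && is.list(report$permanova$line)) {
    pl <- report$permanova$line
    lines <- c(lines, sec("PERMANOVA (line)", c(
      paste0("- pseudo-F: ", num(pl$pseudo_F)),
      paste0("- p: ", num(pl$p_value))
    )))
  }
  if (is.list(report$signature)) {
    s <- report$signature
    lines <- c(lines, sec("Stage-one signature", c(
      paste0("- best ensemble accuracy: ", num(s$best_accuracy)),
      paste0("- final signature size: ", length(s$final_signature)),
      paste0("- final signature: ",
             paste(unlist(s$final_signature), collapse = ", "))
    )))
  }
  if (is.list(report$controls) && is.list(report$controls$line)) {
    cl <- report$controls$line
    lines <- c(lines, sec("Negative controls", c(
      paste0("- line-task control grand mean: ", num(cl$grand_mean),
             " (chance ", num(cl$chance_level), ")"),
      paste0("- stage-one accuracy within chance band: ",
             report$flags$stage1_within_chance_band),
      paste0("- stage-two accuracy within chance band: ",
             report$flags$stage2_within_chance_band)
    )))
  }
  lines
}

#' Validate a run report against the shipped schema
#'
#' Checks that every key required by the schema shipped at
#' `inst/extdata/report-schema.json` is present in the report.
#'
#' @param report A report list (from [render_report()]) or a path to a
#'   `report.json`.
#' @param schema_path Optional alternative schema path.
#' @return `TRUE` invisibly; aborts listing all missing keys otherwise.
#' @export
validate_report <- function(report, schema_path = NULL) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema_path <- schema_path %||%
    system.file("extdata", "report-schema.json", package = "linesig")
  schema <- jsonlite::read_json(schema_path)
  required <- unlist(schema$required)
  missing <- setdiff(required, names(report))
  if (length(missing) > 0) {
    abort(paste0("report is missing required key(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
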