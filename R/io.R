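#' Write an OTU tibble to TSV files
#'
#' Counts are written with OTUs as rows and samples as columns (the common
#' interchange orientation); metadata as a four-column TSV.
#'
#' @param table An OTU tibble.
#' @param counts_path,meta_path Output paths.
#' @return Invisibly, `table`.
#' @export
write_otu_table <- function(table, counts_path, meta_path) {
  check_otu_table(table)
  m <- t(otu_counts(table))
  out <- bind_cols(tibble(otu_id = rownames(m)), as_tibble(m))
  readr::write_tsv(out, counts_path)
  readr::write_tsv(table[, intersect(META_COLS, names(table))], meta_path)
  invisible(table)
}

#' Read an OTU tibble from TSV files
#'
#' The counts file may have samples as rows or as columns; orientation is
#' detected by matching identifiers against the metadata and normalized to
#' samples-as-rows.
#'
#' @param counts_path,meta_path Input paths.
#' @return An OTU tibble.
#' @export
read_otu_table <- function(counts_path, meta_path) {
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  missing <- setdiff(c("sample_id", "line"), names(meta))
  if (length(missing) > 0) {
    abort(paste0("metadata lacks column(s): ", paste(missing, collapse = ", ")))
  }
  raw <- readr::read_tsv(counts_path, show_col_types = FALSE)
  first <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- first
  col_hits <- length(intersect(colnames(m), meta$sample_id))
  row_hits <- length(intersect(rownames(m), meta$sample_id))
  if (col_hits >= row_hits) m <- t(m)  # rows were OTUs
  missing_meta <- setdiff(rownames(m), meta$sample_id)
  missing_counts <- setdiff(meta$sample_id, rownames(m))
  if (length(missing_meta) > 0 || length(missing_counts) > 0) {
    abort(paste0(
      "sample id mismatch between counts and metadata.",
      if (length(missing_meta) > 0) {
        paste0(" In counts only: ", paste(missing_meta, collapse = ", "), ".")
      } else "",
      if (length(missing_counts) > 0) {
        paste0(" In metadata only: ",
               paste(missing_counts, collapse = ", "), ".")
      } else ""
    ))
  }
  m <- m[meta$sample_id, , drop = FALSE]
  out <- bind_cols(as_tibble(meta), as_tibble(m))
  check_otu_table(out)
  out
}

#' Write / read an OTU table in BIOM format
#'
#' Uses the JSON (text) rendering of the BIOM format via the biomformat
#' package; counts only, metadata travels in its own TSV.
#'
#' @param table An OTU tibble.
#' @param path BIOM file path.
#' @return `write_otu_biom()` returns `table` invisibly; `read_otu_biom()`
#'   returns the OTUs-by-samples count matrix.
#' @export
write_otu_biom <- function(table, path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("the 'biomformat' package is required for BIOM output.")
  }
  check_otu_table(table)
  b <- biomformat::make_biom(data = t(otu_counts(table)))
  biomformat::write_biom(b, path)
  invisible(table)
}

#' @rdname write_otu_biom
#' @export
read_otu_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("the 'biomformat' package is required for BIOM input.")
  }
  as.matrix(biomformat::biom_data(biomformat::read_biom(path)))
}

#' Write / read an expression tibble as TSV (genes as rows)
#'
#' @param expr Expression tibble.
#' @param path File path.
#' @return The expression tibble (invisibly for the writer).
#' @export
write_expression <- function(expr, path) {
  m <- t(expr_values(expr))
  out <- bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
  readr::write_tsv(out, path)
  invisible(expr)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  m <- t(m)
  bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
}

#' Read and cross-validate a full set of study inputs
#'
#' Reads counts + metadata (TSV), a Newick tree and an expression TSV,
#' checks that sample ids agree between counts/metadata and expression and
#' that every OTU is a tip of the tree, reporting *all* offending ids.
#'
#' @param counts_path,meta_path,tree_path,expression_path Input paths
#'   (`expression_path` may be `NULL`).
#' @return A list with `table`, `tree` and `expression` (possibly `NULL`).
#' @export
read_inputs <- function(counts_path, meta_path, tree_path,
                        expression_path = NULL) {
  table <- read_otu_table(counts_path, meta_path)
  tree <- ape::read.tree(tree_path)
  problems <- character(0)
  missing_tips <- setdiff(otu_ids(table), tree$tip.label)
  if (length(missing_tips) > 0) {
    problems <- c(problems, paste0("OTUs missing from tree: ",
                                   paste(missing_tips, collapse = ", ")))
  }
  expression <- NULL
  if (!is.null(expression_path)) {
    expression <- read_expression(expression_path)
    only_expr <- setdiff(expression$sample_id, table$sample_id)
    only_counts <- setdiff(table$sample_id, expression$sample_id)
    if (length(only_expr) > 0) {
      problems <- c(problems, paste0("samples only in expression: ",
                                     paste(only_expr, collapse = ", ")))
    }
    if (length(only_counts) > 0) {
      problems <- c(problems, paste0("samples only in counts: ",
                                     paste(only_counts, collapse = ", ")))
    }
    if (length(problems) == 0) {
      expression <- expression[match(table$sample_id, expression$sample_id), ]
    }
  }
  if (length(problems) > 0) {
    abort(paste(c("input cross-validation failed:", problems),
                collapse = "\n"))
  }
  list(table = table, tree = tree, expression = expression)
}
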