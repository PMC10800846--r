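# Internal helpers shared across modules.

# Metadata columns that identify a sample in an OTU tibble; everything else
# is treated as an OTU count column.
META_COLS <- c("sample_id", "line", "tissue", "replicate")

#' Names of the OTU columns of an OTU tibble
#'
#' An OTU tibble is an ordinary tibble with one row per sample, the metadata
#' columns `sample_id`, `line`, `tissue`, `replicate`, and one numeric column
#' of counts per OTU.
#'
#' @param table An OTU tibble.
#' @return Character vector of OTU column names, in table order.
#' @export
otu_ids <- function(table) {
  setdiff(names(table), META_COLS)
}

#' Extract the samples-by-OTUs count matrix from an OTU tibble
#'
#' @param table An OTU tibble (see [otu_ids()]).
#' @return Numeric matrix, rows named by `sample_id`, columns by OTU id.
#' @export
otu_counts <- function(table) {
  ids <- otu_ids(table)
  m <- as.matrix(table[, ids, drop = FALSE])
  rownames(m) <- table$sample_id
  m
}

#' Extract the samples-by-genes expression matrix from an expression tibble
#'
#' An expression tibble has one row per sample, a `sample_id` column, and one
#' numeric column per gene (transcripts per million).
#'
#' @param expr An expression tibble.
#' @return Numeric matrix, rows named by `sample_id`, columns by gene id.
#' @export
expr_values <- function(expr) {
  genes <- setdiff(names(expr), "sample_id")
  m <- as.matrix(expr[, genes, drop = FALSE])
  rownames(m) <- expr$sample_id
  m
}

check_otu_table <- function(table, call = rlang::caller_env()) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    abort("`table` must be a non-empty OTU tibble.", call = call)
  }
  missing <- setdiff(c("sample_id", "line"), names(table))
  if (length(missing) > 0) {
    abort(paste0("`table` lacks required column(s): ",
                 paste(missing, collapse = ", ")), call = call)
  }
  if (anyDuplicated(table$sample_id)) {
    abort("duplicate sample ids in `table`.", call = call)
  }
  ids <- otu_ids(table)
  if (anyDuplicated(ids)) abort("duplicate OTU ids in `table`.", call = call)
  m <- as.matrix(table[, ids, drop = FALSE])
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("OTU counts must be finite and non-negative.", call = call)
  }
  invisible(table)
}

# Deterministic 31-bit hash of (seed, tag) used to derive stage-level child
# seeds from the master seed; stage reproducibility must not depend on the
# order in which stages run.
derive_seed <- function(seed, tag) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(max(1, h))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Shannon entropy (bits) of a class label vector.
entropy_bits <- function(y) {
  p <- table(y)
  p <- p[p > 0] / length(y)
  -sum(p * log2(p))
}
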