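#' Filter OTUs with low total counts
#'
#' Drops every OTU whose total count summed over all samples falls below
#' `min_total`; OTUs with totals at or above the threshold are kept (a
#' 10-count threshold removes OTUs with fewer than 10 reads study-wide).
#' Samples and column order are preserved, and the operation is idempotent.
#'
#' @param table An OTU tibble.
#' @param min_total Minimum total count an OTU needs to be retained
#'   (default 10).
#' @return The filtered OTU tibble.
#' @examples
#' sim <- simulate_otu_table(sim_config(n_otus = 40, n_genes = 100, seed = 1))
#' filtered <- filter_low_count(sim$table)
#' @export
filter_low_count <- function(table, min_total = 10) {
  check_otu_table(table)
  stopifnot(min_total >= 0)
  ids <- otu_ids(table)
  totals <- colSums(otu_counts(table))
  keep <- ids[totals >= min_total]
  table[, c(intersect(META_COLS, names(table)), keep)]
}

#' Partition OTUs by line presence
#'
#' An OTU is "present" in a line if any sample of that line has a positive
#' count. OTUs present anywhere are partitioned into HAS-only, LAS-only and
#' shared sets (the Venn view of the two communities); all-zero OTUs fall in
#' no set.
#'
#' @param table An OTU tibble with both lines in its metadata.
#' @return A tibble with columns `otu_id`, `present_has`, `present_las` and
#'   `partition` (factor: `HAS_only`, `LAS_only`, `both`, `absent`).
#' @export
presence_partition <- function(table) {
  check_otu_table(table)
  if (!all(c("HAS", "LAS") %in% table$line)) {
    abort("`table` must contain samples from both lines.")
  }
  m <- otu_counts(table)
  has <- colSums(m[table$line == "HAS", , drop = FALSE] > 0) > 0
  las <- colSums(m[table$line == "LAS", , drop = FALSE] > 0) > 0
  tibble(
    otu_id = colnames(m),
    present_has = unname(has),
    present_las = unname(las),
    partition = factor(
      case_when(has & las ~ "both",
                has & !las ~ "HAS_only",
                !has & las ~ "LAS_only",
                TRUE ~ "absent"),
      levels = c("HAS_only", "LAS_only", "both", "absent")
    )
  )
}

#' Observed-OTU richness by group
#'
#' Alpha diversity as the number of distinct OTUs with a positive count in
#' at least one sample of the group.
#'
#' @param table An OTU tibble.
#' @param group_by One of `"sample"`, `"line"`, `"tissue"`,
#'   `"line_tissue"`.
#' @return A tibble with the grouping columns and `n_otus`.
#' @export
observed_otus <- function(table, group_by = "sample") {
  check_otu_table(table)
  keys <- switch(group_by,
    sample = "sample_id",
    line = "line",
    tissue = "tissue",
    line_tissue = c("line", "tissue"),
    abort(sprintf("unknown grouping key '%s'.", group_by))
  )
  m <- otu_counts(table) > 0
  table |>
    select(all_of(keys)) |>
    mutate(.row = dplyr::row_number()) |>
    summarise(
      n_otus = sum(colSums(m[.data$.row, , drop = FALSE]) > 0),
      .by = all_of(keys)
    )
}
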