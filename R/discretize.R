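#' Discretize one OTU's per-sample counts into abundance classes
#'
#' Implements the mean-relative discretization used to turn a signature
#' microbe's abundance into a classification target. Two schemes apply:
#'
#' * **with_absent** (some samples have zero counts): let `m` be the mean of
#'   the nonzero counts. Zero counts are `Absent`, counts greater than `m`
#'   are `High`, the rest are `Low`.
#' * **all_present** (every sample has a positive count): let `m` be the mean
#'   of all counts. Counts above `1.5 * m` are `High`, below `0.5 * m` are
#'   `Low`, and counts in the closed interval between the two cutoffs are
#'   `Medium`.
#'
#' Thresholds are mean-relative, so multiplying all counts by a positive
#' constant leaves the classes unchanged. A vector yielding a single class
#' (e.g. all counts equal) is flagged degenerate: two classes are required
#' for downstream classification.
#'
#' @param counts A data frame with columns `sample_id` and `count`, or a
#'   named non-negative numeric vector.
#' @param otu_id Optional identifier recorded in the result.
#' @return An object of class `abundance_classes`: a list with `classes`
#'   (tibble `sample_id`, `count`, `class` with ordered levels
#'   Absent < Low < Medium < High), `scheme`, `mean`, `cutoffs` (count
#'   units) and `degenerate`.
#' @examples
#' discretize_abundance(c(s1 = 0, s2 = 10, s3 = 30))
#' discretize_abundance(c(s1 = 2, s2 = 10, s3 = 30))
#' @export
discretize_abundance <- function(counts, otu_id = NULL) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("sample_id", "count") %in% names(counts)))
    ids <- as.character(counts$sample_id)
    x <- as.double(counts$count)
  } else {
    x <- as.double(counts)
    ids <- names(counts) %||% sprintf("sample_%d", seq_along(x))
  }
  if (length(x) == 0 || any(!is.finite(x)) || any(x < 0)) {
    abort("`counts` must be non-negative finite numbers.")
  }
  if (all(x == 0)) abort("all counts are zero; nothing to discretize.")

  lv <- c("Absent", "Low", "Medium", "High")
  eps <- 1e-9  # boundary comparisons on the scale-free ratio x/m
  if (any(x == 0)) {
    scheme <- "with_absent"
    m <- mean(x[x > 0])
    cutoffs <- c(low_high = m)
    r <- x / m
    cl <- ifelse(x == 0, "Absent", ifelse(r > 1 + eps, "High", "Low"))
  } else {
    scheme <- "all_present"
    m <- mean(x)
    cutoffs <- c(low = 0.5 * m, high = 1.5 * m)
    r <- x / m
    cl <- ifelse(r > 1.5 + eps, "High", ifelse(r < 0.5 - eps, "Low", "Medium"))
  }
  cl <- factor(cl, levels = lv, ordered = TRUE)
  structure(list(
    otu_id = otu_id,
    classes = tibble(sample_id = ids, count = x, class = cl),
    scheme = scheme,
    mean = m,
    cutoffs = cutoffs,
    degenerate = length(unique(cl)) < 2
  ), class = "abundance_classes")
}

#' Ordinal encoding of abundance classes
#'
#' Maps each sample's class to its ordinal step within the scheme's realized
#' ladder: `Absent`/`Low`/`High` -> 0/1/2 under `with_absent`, and
#' `Low`/`Medium`/`High` -> 0/1/2 under `all_present`.
#'
#' @param x An `abundance_classes` object.
#' @return Named integer vector (0-based ordinal steps) by sample id.
#' @export
class_ordinal <- function(x) {
  stopifnot(inherits(x, "abundance_classes"))
  ladder <- if (x$scheme == "with_absent") {
    c(Absent = 0L, Low = 1L, High = 2L)
  } else {
    c(Low = 0L, Medium = 1L, High = 2L)
  }
  setNames(ladder[as.character(x$classes$class)], x$classes$sample_id)
}

#' @export
print.abundance_classes <- function(x, ...) {
  cat(sprintf("<abundance_classes%s> scheme=%s mean=%.4g%s\n",
              if (is.null(x$otu_id)) "" else paste0(" ", x$otu_id),
              x$scheme, x$mean,
              if (x$degenerate) " [degenerate]" else ""))
  print(table(x$classes$class))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.abundance_classes <- function(x, ...) {
  out <- x$classes
  if (!is.null(x$otu_id)) out <- mutate(out, otu_id = x$otu_id, .before = 1)
  out
}

#' Build a Table-1-style class grid for several OTUs
#'
#' Discretizes each listed OTU over the samples of `table` and assembles the
#' per-sample class letters (A/L/M/H) into one tibble, rows = OTUs,
#' columns = samples.
#'
#' @param table An OTU tibble.
#' @param otus Character vector of OTU ids to discretize.
#' @return A list with `grid` (tibble: `otu_id`, then one letter column per
#'   sample), `details` (list of `abundance_classes`) and `degenerate`
#'   (character vector of OTUs yielding a single class, which are excluded
#'   from stage-two classification).
#' @export
class_grid <- function(table, otus) {
  check_otu_table(table)
  missing <- setdiff(otus, otu_ids(table))
  if (length(missing) > 0) {
    abort(paste0("OTUs absent from table: ", paste(missing, collapse = ", ")))
  }
  details <- lapply(otus, function(o) {
    discretize_abundance(tibble(sample_id = table$sample_id,
                                count = table[[o]]), otu_id = o)
  })
  names(details) <- otus
  letters4 <- c(Absent = "A", Low = "L", Medium = "M", High = "H")
  rows <- lapply(details, function(d) {
    v <- setNames(letters4[as.character(d$classes$class)],
                  d$classes$sample_id)
    as_tibble(as.list(v))
  })
  grid <- bind_cols(tibble(otu_id = otus), bind_rows(rows))
  degenerate <- names(details)[vapply(details, function(d) d$degenerate,
                                      logical(1))]
  list(grid = grid, details = details, degenerate = degenerate)
}
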