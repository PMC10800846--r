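#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: eigen-decomposition of the double-centered
#' squared-distance matrix. Axes are ordered by decreasing eigenvalue;
#' negative eigenvalues are reported but their axes dropped, and explained
#' fractions are taken over the positive eigenvalues.
#'
#' @param d A `dist` object or symmetric distance matrix with zero diagonal.
#' @param n_axes Number of axes to return (default 2; capped at the number
#'   of positive eigenvalues).
#' @return An object of class `pcoa_ord`: list with `coordinates` (tibble:
#'   `sample_id`, `Axis1`, ...), `eigenvalues` (all, decreasing) and
#'   `explained` (fraction per returned axis).
#' @export
ordinate_pcoa <- function(d, n_axes = 2) {
  dm <- as_distance_matrix(d)
  n <- nrow(dm)
  k <- min(n_axes, n - 1)
  fit <- cmdscale(stats::as.dist(dm), k = k, eig = TRUE)
  eig <- fit$eig
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  keep <- min(k, pos)
  pts <- fit$points[, seq_len(keep), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(keep))
  explained <- if (pos > 0) eig[seq_len(keep)] / sum(eig[eig > 0]) else numeric(0)
  structure(list(
    coordinates = bind_cols(tibble(sample_id = rownames(dm)), as_tibble(pts)),
    eigenvalues = eig,
    explained = explained
  ), class = "pcoa_ord")
}

as_distance_matrix <- function(d) {
  if (inherits(d, "dist")) {
    dm <- as.matrix(d)
  } else {
    dm <- as.matrix(d)
    if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8)) {
      abort("`d` must be a symmetric distance matrix.")
    }
  }
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- sprintf("sample_%d", seq_len(nrow(dm)))
  }
  dm
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("<pcoa_ord> %d samples, %d axes\n",
              nrow(x$coordinates), length(x$explained)))
  if (length(x$explained) > 0) {
    cat("  explained:",
        paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pcoa_ord <- function(x, ...) x$coordinates

#' @exportS3Method generics::glance
glance.pcoa_ord <- function(x, ...) {
  tibble(n_samples = nrow(x$coordinates),
         n_axes = length(x$explained),
         n_negative_eig = sum(x$eigenvalues < 0),
         explained_axis1 = x$explained[1] %||% NA_real_,
         explained_axis2 = if (length(x$explained) >= 2) x$explained[2] else NA_real_)
}

#' @param object A `pcoa_ord` object.
#' @param colour_by,shape_by Optional per-sample vectors (or metadata tibble
#'   columns) used for the aesthetics.
#' @param ... Unused.
#' @rdname ordinate_pcoa
#' @exportS3Method ggplot2::autoplot
autoplot.pcoa_ord <- function(object, colour_by = NULL, shape_by = NULL, ...) {
  df <- object$coordinates
  if (ncol(df) < 3) abort("need at least two axes to plot.")
  df$colour_by <- colour_by %||% "sample"
  df$shape_by <- shape_by %||% "sample"
  lab <- function(i) {
    sprintf("Axis %d (%.1f%%)", i, 100 * object$explained[i])
  }
  ggplot(df, aes(.data$Axis1, .data$Axis2,
                 colour = .data$colour_by, shape = .data$shape_by)) +
    geom_point(size = 2) +
    labs(x = lab(1), y = lab(2), colour = NULL, shape = NULL) +
    theme_minimal()
}
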