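# Clade analysis: complete-linkage clustering of cells on Euclidean distance
# of binned copy number, retention of clades with more than three cells, and
# Holm-adjusted per-bin Welch comparisons between clade pairs at fine
# resolution.

#' Detect clades of cells from a binned copy-number matrix
#'
#' Agglomerative clustering (complete linkage on Euclidean distance of
#' per-cell bin values, typically at 500 kb). The dendrogram is cut either
#' at a requested clade count or at a height. Clades with fewer than
#' `min_cells` cells (default 4, i.e. "more than three cells") are excluded
#' from downstream comparisons but kept in the labeling.
#'
#' @param mat a [cn_bin_matrix] of cells.
#' @param n_clades number of flat clades (mutually exclusive with `height`).
#' @param height dendrogram cut height.
#' @param min_cells minimum clade size to retain (default 4).
#' @return list of class `clade_result`: `labels` (per cell), `sizes`,
#'   `retained` (clade ids with size >= min_cells), `hclust`, `min_cells`.
#' @export
detect_clades <- function(mat, n_clades = NULL, height = NULL, min_cells = 4) {
  v <- mat$values
  if (nrow(v) < 2 * min_cells)
    stop_named("need at least %d cells", 2 * min_cells)
  if (is.null(n_clades) && is.null(height))
    stop_named("supply either n_clades or height (no default cut is inferred)")
  if (!is.null(n_clades) && n_clades > nrow(v))
    stop_named("requested %d clades from %d cells", n_clades, nrow(v))
  complete <- !apply(is.na(v), 2, any)
  hc <- stats::hclust(stats::dist(v[, complete, drop = FALSE]),
                      method = "complete")
  labels <- if (!is.null(n_clades)) stats::cutree(hc, k = n_clades)
            else stats::cutree(hc, h = height)
  sizes <- table(labels)
  retained <- as.integer(names(sizes)[sizes >= min_cells])
  structure(list(labels = labels, sizes = sizes, retained = retained,
                 hclust = hc, min_cells = min_cells),
            class = "clade_result")
}

#' @export
print.clade_result <- function(x, ...) {
  cat(sprintf("clade_result: %d cells in %d clades (retained >= %d cells: %s)\n",
              length(x$labels), length(x$sizes), x$min_cells,
              paste(x$retained, collapse = ", ")))
  invisible(x)
}

#' Per-bin differential copy number between two clades
#'
#' Welch two-sample t-test of absolute copy number per bin (typically at
#' 20 kb resolution) between cells of two retained clades, with
#' Holm-Bonferroni adjustment across all tested bins of the comparison.
#' Bins with zero variance in both clades and no mean difference are
#' assigned p = 1 and flagged `degenerate`.
#'
#' @param mat a [cn_bin_matrix] (fine resolution).
#' @param labels per-cell clade labels (as from [detect_clades]; cell order
#'   must match the matrix rows).
#' @param clade_x,clade_y the two clade ids to compare.
#' @param min_cells minimum clade size (both clades must reach it).
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame per bin: chrom, start, end, mean_x, mean_y, statistic,
#'   df, p_value, p_adjusted, significant, degenerate.
#' @export
clade_differential_bins <- function(mat, labels, clade_x, clade_y,
                                    min_cells = 4, alpha = 0.05) {
  v <- mat$values
  stopifnot(length(labels) == nrow(v))
  ix <- which(labels == clade_x); iy <- which(labels == clade_y)
  if (length(ix) < min_cells || length(iy) < min_cells)
    stop_named("both clades must have at least %d cells (got %d and %d)",
               min_cells, length(ix), length(iy))
  X <- v[ix, , drop = FALSE]; Y <- v[iy, , drop = FALSE]
  nx <- colSums(!is.na(X)); ny <- colSums(!is.na(Y))
  mx <- colMeans(X, na.rm = TRUE); my <- colMeans(Y, na.rm = TRUE)
  vx <- apply(X, 2, stats::var, na.rm = TRUE)
  vy <- apply(Y, 2, stats::var, na.rm = TRUE)
  se2 <- vx / nx + vy / ny
  statistic <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(statistic), df)
  degenerate <- se2 == 0 | !is.finite(p)
  p[degenerate] <- 1
  testable <- nx >= 2 & ny >= 2
  p_adj <- rep(NA_real_, length(p))
  p_adj[testable] <- holm_adjust(p[testable])
  data.frame(mat$bins, n_x = nx, n_y = ny, mean_x = mx, mean_y = my,
             statistic = statistic, df = df, p_value = p,
             p_adjusted = p_adj,
             significant = !is.na(p_adj) & p_adj < alpha,
             degenerate = degenerate)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Wrapper around `stats::p.adjust(method = "holm")`: sorted ascending,
#' `adj_(i) = max_{j<=i} min(1, (m - j + 1) p_(j))`, mapped back to the
#' input order.
#'
#' @param p raw p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_named("p-values outside [0, 1]")
  stats::p.adjust(p, method = "holm")
}
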