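# Gene-level copy number and its concordance with expression: assignment of
# segment CN to genes, median-of-ratios normalization, the lowest-k
# concordance metric, per-gene R^2, and amplification ranking.

#' Assign gene-level absolute copy number from segmented profiles
#'
#' Default rule: each gene takes the copy number of the single overlapping
#' segment with the largest overlap ("overlap"). Alternatives:
#' `"weighted"` (overlap-length-weighted mean over all overlapping
#' segments) and `"midpoint"` (segment containing the gene midpoint).
#' Genes with no overlapping segment are `NA`.
#'
#' @param profiles list of [cn_profile] (one per sample) or a single profile.
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`; strand ignored), as from [read_gene_bed].
#' @param rule assignment rule.
#' @return genes x samples numeric matrix with a `provenance` attribute
#'   (same shape, index of the supplying segment, NA when missing).
#' @export
assign_gene_cn <- function(profiles, genes,
                           rule = c("overlap", "weighted", "midpoint")) {
  rule <- match.arg(rule)
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  genes <- validate_gene_table(genes)
  if (nrow(genes) == 0) stop_named("gene list is empty")
  gr_genes <- GRanges(genes$chrom, IRanges(genes$start + 1, genes$end))
  sample_ids <- vapply(profiles, attr, "", "sample_id")
  cn <- matrix(NA_real_, nrow(genes), length(profiles),
               dimnames = list(genes$gene_id, sample_ids))
  prov <- matrix(NA_integer_, nrow(genes), length(profiles),
                 dimnames = dimnames(cn))
  for (s in seq_along(profiles)) {
    seg <- profiles[[s]]
    gr_seg <- GRanges(seg$chrom, IRanges(seg$start + 1, seg$end))
    hits <- findOverlaps(gr_genes, gr_seg)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- width(pintersect(gr_genes[qh], gr_seg[sh]))
    for (g in unique(qh)) {
      sel <- which(qh == g)
      if (rule == "overlap") {
        best <- sel[which.max(ov[sel])]
        cn[g, s] <- seg$cn[sh[best]]
        prov[g, s] <- sh[best]
      } else if (rule == "weighted") {
        cn[g, s] <- sum(ov[sel] * seg$cn[sh[sel]]) / sum(ov[sel])
        prov[g, s] <- sh[sel[which.max(ov[sel])]]
      } else {
        mid <- (genes$start[g] + genes$end[g]) / 2
        inseg <- sel[seg$start[sh[sel]] <= mid & mid < seg$end[sh[sel]]]
        if (length(inseg)) {
          cn[g, s] <- seg$cn[sh[inseg[1]]]
          prov[g, s] <- sh[inseg[1]]
        }
      }
    }
  }
  attr(cn, "provenance") <- prov
  cn
}

#' Median-of-ratios size-factor normalization
#'
#' The reference is the per-gene geometric mean across samples (genes with
#' any zero count are excluded from factor estimation); each sample's size
#' factor is the median of its count/reference ratios, taken on the log
#' scale (for an even number of genes the two middle ratios are averaged
#' geometrically, which keeps the factors multiplicatively consistent), and
#' counts are divided by it. Factors are standardized to geometric mean 1 —
#' size factors are only defined up to a global constant, and this
#' convention makes the operation exactly idempotent.
#'
#' @param counts nonnegative genes x samples count matrix (>= 2 samples).
#' @return list with `normalized` matrix and `size_factors`.
#' @export
size_factor_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop_named("need >= 2 samples")
  if (any(counts < 0)) stop_named("negative counts")
  allpos <- rowSums(counts == 0) == 0
  if (!any(allpos))
    stop_named("no gene with all-positive counts: size factors undefined")
  ref <- exp(rowMeans(log(counts[allpos, , drop = FALSE])))
  size_factors <- apply(counts[allpos, , drop = FALSE], 2,
                        function(col) exp(stats::median(log(col / ref))))
  size_factors <- size_factors / exp(mean(log(size_factors)))
  list(normalized = sweep(counts, 2, size_factors, "/"),
       size_factors = size_factors)
}

#' Lowest-k copy-number/expression concordance metric
#'
#' Averages the expression of the `k` samples with the lowest copy number
#' for the gene and returns the fraction of the remaining `n - k` samples
#' whose expression is strictly higher than that average. With 11 samples
#' and k = 3 the metric ranges over 0/8 .. 8/8; high values indicate
#' dosage-driven expression. Ties at the k-th lowest CN are broken by
#' sample order (deterministic, expression-blind).
#'
#' @param cn_row per-sample absolute copy number for one gene.
#' @param expr_row matching per-sample expression.
#' @param k number of lowest-CN samples to average (default 3).
#' @return fraction in \[0, 1\].
#' @export
lowest_k_metric <- function(cn_row, expr_row, k = 3) {
  keep <- !is.na(cn_row) & !is.na(expr_row)
  cn_row <- cn_row[keep]; expr_row <- expr_row[keep]
  n <- length(cn_row)
  if (n <= k) stop_named("need more than k = %d samples (got %d)", k, n)
  low <- order(cn_row)[seq_len(k)]   # order() breaks ties by position
  m <- mean(expr_row[low])
  sum(expr_row[-low] > m) / (n - k)
}

#' Squared Pearson correlation between copy number and expression
#'
#' @param cn_row,expr_row paired per-sample values (>= 3 non-missing pairs).
#' @return R^2 in \[0, 1\], or NA when either vector has zero variance.
#' @export
cn_expression_r2 <- function(cn_row, expr_row) {
  keep <- !is.na(cn_row) & !is.na(expr_row)
  if (sum(keep) < 3) stop_named("need >= 3 paired values")
  if (stats::sd(cn_row[keep]) == 0 || stats::sd(expr_row[keep]) == 0)
    return(NA_real_)
  stats::cor(cn_row[keep], expr_row[keep])^2
}

#' Per-gene concordance table
#'
#' @param cn genes x samples copy-number matrix.
#' @param expr genes x samples expression matrix (same dimnames).
#' @param k lowest-k parameter.
#' @return data.frame: gene, mean_cn, metric, r_squared.
#' @export
concordance_table <- function(cn, expr, k = 3) {
  stopifnot(all(rownames(cn) == rownames(expr)))
  data.frame(
    gene = rownames(cn),
    mean_cn = rowMeans(cn, na.rm = TRUE),
    metric = vapply(seq_len(nrow(cn)), function(i)
      lowest_k_metric(cn[i, ], expr[i, ], k), 0),
    r_squared = vapply(seq_len(nrow(cn)), function(i)
      cn_expression_r2(cn[i, ], expr[i, ]), 0),
    row.names = NULL)
}

#' Robustness of the lowest-k metric to the choice of k
#'
#' Recomputes the metric at each k and reports the pairwise Pearson
#' correlations, across genes, of the averaged lowest-k expression values.
#'
#' @param cn,expr genes x samples matrices.
#' @param ks values of k to compare (default 2, 3, 4).
#' @return list with `metrics` (genes x ks), `low_means` (genes x ks
#'   averaged lowest-k expression), `correlations` (ks x ks).
#' @export
metric_k_robustness <- function(cn, expr, ks = c(2, 3, 4)) {
  n <- ncol(cn)
  if (any(ks > n - 1)) stop_named("k values must be < number of samples")
  low_mean <- function(i, k) {
    keep <- !is.na(cn[i, ]) & !is.na(expr[i, ])
    mean(expr[i, keep][order(cn[i, keep])[seq_len(k)]])
  }
  metrics <- sapply(ks, function(k)
    vapply(seq_len(nrow(cn)), function(i)
      lowest_k_metric(cn[i, ], expr[i, ], k), 0))
  low_means <- sapply(ks, function(k)
    vapply(seq_len(nrow(cn)), function(i) low_mean(i, k), 0))
  colnames(metrics) <- colnames(low_means) <- paste0("k", ks)
  list(metrics = metrics, low_means = low_means,
       correlations = stats::cor(low_means))
}

#' Rank genes by mean copy number across samples
#'
#' @param cn genes x samples copy-number matrix.
#' @return data.frame ordered by decreasing mean CN (ties broken by gene
#'   id), columns `gene` and `mean_cn`.
#' @export
rank_amplified_genes <- function(cn) {
  mean_cn <- rowMeans(cn, na.rm = TRUE)
  ord <- order(-mean_cn, rownames(cn))
  data.frame(gene = rownames(cn)[ord], mean_cn = mean_cn[ord],
             row.names = NULL)
}
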