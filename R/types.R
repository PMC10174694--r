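# Domain containers. Light S3: plain data structures plus validators, in the
# style of segmented copy-number tooling (data frames for segments, matrices
# with a bin table for binned genomes).

#' Segmented absolute copy-number profile
#'
#' One sample's absolute copy number as an ordered set of genomic segments.
#' Coordinates are 0-based half-open throughout the package.
#'
#' @param sample_id sample identifier.
#' @param segments data.frame with columns `chrom`, `start`, `end`, `cn`.
#' @return object of class `cn_profile`: the segment data.frame with a
#'   `sample_id` attribute, sorted by (chromosome, start).
#' @export
cn_profile <- function(sample_id, segments) {
  stopifnot(is.data.frame(segments))
  need <- c("chrom", "start", "end", "cn")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop_named("segment table lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(segments) == 0) stop_named("profile '%s' has no segments", sample_id)
  segments <- segments[order_genomic(segments$chrom, segments$start), need,
                       drop = FALSE]
  rownames(segments) <- NULL
  validate_segments(segments)
  structure(segments, sample_id = as.character(sample_id),
            class = c("cn_profile", "data.frame"))
}

validate_segments <- function(segments) {
  if (any(segments$start >= segments$end))
    stop_named("segment with start >= end")
  if (any(segments$cn < 0)) stop_named("negative copy number in segments")
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop_named("overlapping segments on %s", ch)
  }
  invisible(segments)
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("cn_profile '%s': %d segments on %d chromosome(s)\n",
              attr(x, "sample_id"), nrow(x), length(unique(x$chrom))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Binned copy-number matrix (cells or samples x genomic bins)
#'
#' @param values numeric matrix, units in rows, bins in columns; `NA` encodes
#'   bins with no information (never 0, which is a real copy number).
#' @param bins data.frame with columns `chrom`, `start`, `end`, sorted by
#'   (chromosome, start); all bins share `bin_size` width except possibly the
#'   terminal bin of each chromosome.
#' @param bin_size bin width in base pairs.
#' @return object of class `cn_bin_matrix` (a list with `values`, `bins`,
#'   `bin_size`).
#' @export
cn_bin_matrix <- function(values, bins, bin_size) {
  values <- as.matrix(values)
  stopifnot(is.data.frame(bins), all(c("chrom", "start", "end") %in% names(bins)))
  if (ncol(values) != nrow(bins))
    stop_named("values has %d columns but %d bins supplied", ncol(values), nrow(bins))
  if (any(values < 0, na.rm = TRUE)) stop_named("negative copy-number entries")
  if (any(bins$start >= bins$end)) stop_named("bin with start >= end")
  ord <- order_genomic(bins$chrom, bins$start)
  if (!identical(ord, seq_len(nrow(bins)))) {
    bins <- bins[ord, , drop = FALSE]
    values <- values[, ord, drop = FALSE]
  }
  rownames(bins) <- NULL
  if (is.null(rownames(values)))
    rownames(values) <- paste0("unit", seq_len(nrow(values)))
  structure(list(values = values, bins = bins, bin_size = as.integer(bin_size)),
            class = "cn_bin_matrix")
}

#' @export
print.cn_bin_matrix <- function(x, ...) {
  cat(sprintf("cn_bin_matrix: %d units x %d bins (%d bp bins, %d chromosome(s))\n",
              nrow(x$values), ncol(x$values), x$bin_size,
              length(unique(x$bins$chrom))))
  invisible(x)
}

#' @export
dim.cn_bin_matrix <- function(x) dim(x$values)

#' Copy-number signature activity table
#'
#' Samples x K signature activities; each row is a composition on the unit
#' simplex (sums to 1, entries in \[0, 1\]).
#'
#' @param activities numeric matrix with sample ids as rownames and signature
#'   ids (e.g. `s1..s7`) as colnames.
#' @param tol tolerance on the row-sum-to-1 invariant.
#' @return validated matrix of class `signature_activities`.
#' @export
signature_activities <- function(activities, tol = 1e-6) {
  activities <- as.matrix(activities)
  if (is.null(colnames(activities)))
    colnames(activities) <- paste0("s", seq_len(ncol(activities)))
  if (is.null(rownames(activities)))
    rownames(activities) <- paste0("sample", seq_len(nrow(activities)))
  if (any(activities < -tol) || any(activities > 1 + tol))
    stop_named("signature activities must lie in [0, 1]")
  bad <- abs(rowSums(activities) - 1) > tol
  if (any(bad))
    stop_named("activity row(s) not summing to 1: %s",
               paste(rownames(activities)[bad], collapse = ", "))
  class(activities) <- c("signature_activities", class(activities))
  activities
}

#' Validate a dose-response plate table
#'
#' Long-format plate measurements. Every (compound, sample) group with
#' treated rows must have at least two distinct positive doses and at least
#' one control row.
#'
#' @param tab data.frame with columns `compound`, `sample`, `dose_uM`,
#'   `replicate`, `response`, `is_control` (0/1; control rows may carry an
#'   empty/NA dose).
#' @return the validated data.frame (invisibly classed `dose_response`).
#' @export
dose_response_table <- function(tab) {
  need <- c("compound", "sample", "dose_uM", "replicate", "response", "is_control")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_named("dose-response table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(tab$response < 0, na.rm = TRUE)) stop_named("negative response values")
  for (key in unique(paste(tab$compound, tab$sample, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    g <- tab[tab$compound == parts[1] & tab$sample == parts[2], ]
    treated <- g[g$is_control == 0, ]
    if (nrow(treated)) {
      if (length(unique(treated$dose_uM[treated$dose_uM > 0])) < 2)
        stop_named("group (%s, %s) has fewer than 2 distinct positive doses",
                   parts[1], parts[2])
      if (!any(g$is_control == 1))
        stop_named("group (%s, %s) has no control wells", parts[1], parts[2])
    }
  }
  class(tab) <- unique(c("dose_response", class(tab)))
  invisible(tab)
}

validate_gene_table <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop_named("gene table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(genes$start >= genes$end)) stop_named("gene with start >= end")
  if (is.null(genes$strand)) genes$strand <- "."
  genes
}
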