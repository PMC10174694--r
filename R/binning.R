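# Genomic binning: segment -> bin projection, rebinning, per-profile summaries.
# Overlap arithmetic goes through GenomicRanges, the standard container for
# this kind of work.

#' @importFrom GenomicRanges GRanges findOverlaps pintersect
#' @importFrom IRanges IRanges width
NULL

#' Tile chromosomes into fixed-width bins
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size bin width in bp; the terminal bin of each chromosome is
#'   truncated at the chromosome end.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
make_bins <- function(chrom_lengths, bin_size) {
  stopifnot(bin_size > 0, !is.null(names(chrom_lengths)))
  chroms <- names(chrom_lengths)[order(chrom_rank(names(chrom_lengths)))]
  out <- lapply(chroms, function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, len))
  })
  do.call(rbind, out)
}

#' Project a segmented profile onto fixed-width bins
#'
#' Each bin takes the length-weighted mean copy number of the segments
#' overlapping it; bins with no overlapping segment are `NA`.
#'
#' @param profile a [cn_profile].
#' @param bin_size bin width in bp.
#' @param chrom_lengths optional named vector bounding the bins; defaults to
#'   the maximum segment end per chromosome.
#' @return a single-unit [cn_bin_matrix].
#' @export
segments_to_bins <- function(profile, bin_size, chrom_lengths = NULL) {
  stopifnot(bin_size > 0)
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(profile$end, profile$chrom, max)
  bins <- make_bins(chrom_lengths, bin_size)
  gr_bins <- GRanges(bins$chrom, IRanges(bins$start + 1, bins$end))
  gr_seg <- GRanges(profile$chrom, IRanges(profile$start + 1, profile$end))
  hits <- findOverlaps(gr_bins, gr_seg)
  ov <- width(pintersect(gr_bins[S4Vectors::queryHits(hits)],
                         gr_seg[S4Vectors::subjectHits(hits)]))
  vals <- rep(NA_real_, nrow(bins))
  if (length(hits)) {
    wsum <- tapply(ov, S4Vectors::queryHits(hits), sum)
    csum <- tapply(ov * profile$cn[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), sum)
    idx <- as.integer(names(wsum))
    vals[idx] <- csum / wsum
  }
  m <- matrix(vals, nrow = 1,
              dimnames = list(attr(profile, "sample_id"), NULL))
  cn_bin_matrix(m, bins, bin_size)
}

#' Aggregate a binned matrix to a coarser bin size
#'
#' The target bin size must be an integer multiple of the current one. Each
#' coarse bin is the mean of its non-missing constituent fine bins, per unit;
#' a coarse bin whose fine bins are all missing is missing.
#'
#' @param mat a [cn_bin_matrix].
#' @param target_bin_size coarse bin width in bp.
#' @return a [cn_bin_matrix] at the coarser resolution.
#' @export
rebin <- function(mat, target_bin_size) {
  if (target_bin_size %% mat$bin_size != 0)
    stop_named("target bin size %d is not a multiple of %d",
               target_bin_size, mat$bin_size)
  if (target_bin_size == mat$bin_size) return(mat)
  key <- paste(mat$bins$chrom, mat$bins$start %/% target_bin_size, sep = "\r")
  key <- factor(key, levels = unique(key))  # preserves genomic order
  groups <- split(seq_len(nrow(mat$bins)), key)
  coarse_bins <- do.call(rbind, lapply(groups, function(ix) {
    data.frame(chrom = mat$bins$chrom[ix[1]],
               start = (mat$bins$start[ix[1]] %/% target_bin_size) * target_bin_size,
               end = max(mat$bins$end[ix]))
  }))
  vals <- vapply(groups, function(ix) {
    rowMeans(mat$values[, ix, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(mat$values)))
  if (nrow(mat$values) == 1) vals <- matrix(vals, nrow = 1)
  vals[is.nan(vals)] <- NA_real_
  rownames(vals) <- rownames(mat$values)
  cn_bin_matrix(vals, coarse_bins, target_bin_size)
}

#' Segment count and average ploidy of a profile
#'
#' Average ploidy is the segment-length-weighted mean absolute copy number.
#'
#' @param profile a [cn_profile].
#' @return list with `segment_count` and `average_ploidy`.
#' @export
profile_summary <- function(profile) {
  if (nrow(profile) == 0) stop_named("empty profile")
  w <- profile$end - profile$start
  list(segment_count = nrow(profile),
       average_ploidy = sum(w * profile$cn) / sum(w))
}

#' Subset a binned matrix by unit
#' @param mat a [cn_bin_matrix].
#' @param units character or integer index of units to keep.
#' @return a [cn_bin_matrix].
#' @export
subset_units <- function(mat, units) {
  cn_bin_matrix(mat$values[units, , drop = FALSE], mat$bins, mat$bin_size)
}
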