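# Readers and writers for the package's plain-text formats. All readers
# normalize genomic coordinates to 0-based half-open; the tsv1 dialect
# (1-based inclusive) is converted at this boundary and nowhere else.

#' Read a segmented copy-number profile
#'
#' BED4-like TSV with columns `chrom start end cn`. A header line prefixed
#' with `#` is allowed and skipped. `dialect = "bed0"` is 0-based half-open;
#' `"tsv1"` is 1-based inclusive and is converted on input (start - 1).
#'
#' @param path file path.
#' @param dialect coordinate dialect, `"bed0"` (default) or `"tsv1"`.
#' @param sample_id sample identifier; defaults to the file base name.
#' @return a [cn_profile].
#' @export
read_segments <- function(path, dialect = c("bed0", "tsv1"), sample_id = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop_named("no segment rows in %s", path)
  fields <- strsplit(lines, "\t| +")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 4 || anyNA(suppressWarnings(as.numeric(f[2:4]))))
      stop_named("malformed segment row at line %d of %s", i, path)
  }
  seg <- data.frame(
    chrom = vapply(fields, `[`, "", 1),
    start = as.numeric(vapply(fields, `[`, "", 2)),
    end   = as.numeric(vapply(fields, `[`, "", 3)),
    cn    = as.numeric(vapply(fields, `[`, "", 4)),
    stringsAsFactors = FALSE)
  if (dialect == "tsv1") seg$start <- seg$start - 1
  cn_profile(sample_id %||% sub("\\.[^.]*$", "", basename(path)), seg)
}

#' Write a segmented profile as BED4-like TSV (0-based half-open)
#' @param profile a [cn_profile].
#' @param path output path.
#' @export
write_segments <- function(profile, path) {
  writeLines(c("#chrom\tstart\tend\tcn",
               sprintf("%s\t%d\t%d\t%.10g", profile$chrom,
                       as.integer(profile$start), as.integer(profile$end),
                       profile$cn)), path)
  invisible(path)
}

#' Read/write a binned copy-number matrix
#'
#' TSV with columns `chrom`, `start`, `end`, then one column per unit (cell
#' or sample); missing bins are `NA`.
#'
#' @param path file path.
#' @param bin_size bin width in bp; inferred as the modal bin width when NULL.
#' @return a [cn_bin_matrix].
#' @export
read_cn_bin_matrix <- function(path, bin_size = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(tab)))
    stop_named("binned matrix file lacks column(s): %s",
               paste(setdiff(need, names(tab)), collapse = ", "))
  unit_cols <- setdiff(names(tab), need)
  if (!length(unit_cols)) stop_named("binned matrix file has no unit columns")
  values <- t(as.matrix(tab[, unit_cols, drop = FALSE]))
  rownames(values) <- unit_cols
  widths <- tab$end - tab$start
  bin_size <- bin_size %||% as.integer(names(sort(table(widths), decreasing = TRUE))[1])
  cn_bin_matrix(values, tab[, need], bin_size)
}

#' @rdname read_cn_bin_matrix
#' @param mat a [cn_bin_matrix].
#' @export
write_cn_bin_matrix <- function(mat, path) {
  out <- cbind(mat$bins,
               as.data.frame(t(mat$values), check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a signature activity table
#'
#' TSV with a `sample` column followed by one column per signature
#' (`s1 .. sK`). Rows must sum to 1 within 1e-6.
#'
#' @param path file path.
#' @return a [signature_activities] matrix.
#' @export
read_signature_activities <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!"sample" %in% names(tab))
    stop_named("activity file lacks column: sample")
  m <- as.matrix(tab[, setdiff(names(tab), "sample"), drop = FALSE])
  rownames(m) <- tab$sample
  signature_activities(m)
}

#' @rdname read_signature_activities
#' @param activities a [signature_activities] matrix.
#' @export
write_signature_activities <- function(activities, path) {
  out <- data.frame(sample = rownames(activities),
                    as.data.frame(unclass(activities), check.names = FALSE),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a normalized expression matrix
#'
#' TSV with a `gene` column followed by one column per sample. Values are
#' nonnegative normalized counts.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!"gene" %in% names(tab)) stop_named("expression file lacks column: gene")
  m <- as.matrix(tab[, setdiff(names(tab), "gene"), drop = FALSE])
  rownames(m) <- tab$gene
  if (any(m < 0, na.rm = TRUE)) stop_named("negative expression values")
  m
}

#' @rdname read_expression
#' @param mat genes x samples matrix.
#' @export
write_expression <- function(mat, path) {
  out <- data.frame(gene = rownames(mat),
                    as.data.frame(mat, check.names = FALSE), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write gene annotations (BED)
#'
#' BED with columns chrom, start, end, name and optionally score and strand;
#' coordinates 0-based half-open. Strand is read but ignored by all
#' computations.
#'
#' @param path file path.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t| +")
  n <- lengths(fields)
  if (any(n < 4)) stop_named("BED row with fewer than 4 fields")
  genes <- data.frame(
    gene_id = vapply(fields, `[`, "", 4),
    chrom = vapply(fields, `[`, "", 1),
    start = as.numeric(vapply(fields, `[`, "", 2)),
    end = as.numeric(vapply(fields, `[`, "", 3)),
    strand = vapply(seq_along(fields), function(i)
      if (n[i] >= 6) fields[[i]][6] else ".", ""),
    stringsAsFactors = FALSE)
  validate_gene_table(genes)
}

#' @rdname read_gene_bed
#' @param genes data.frame as returned by `read_gene_bed`.
#' @export
write_gene_bed <- function(genes, path) {
  genes <- validate_gene_table(genes)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom,
                     as.integer(genes$start), as.integer(genes$end),
                     genes$gene_id, genes$strand), path)
  invisible(path)
}

#' Read/write a dose-response plate table (CSV)
#'
#' Columns `compound,sample,dose_uM,replicate,response,is_control`;
#' `is_control` is 0/1 and control rows may have an empty dose.
#'
#' @param path file path.
#' @return validated data.frame (see [dose_response_table]).
#' @export
read_dose_response <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("compound", "sample", "dose_uM", "replicate", "response", "is_control")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_named("dose-response file lacks column(s): %s", paste(miss, collapse = ", "))
  tab$dose_uM <- suppressWarnings(as.numeric(tab$dose_uM))
  dose_response_table(tab)
  tab
}

#' @rdname read_dose_response
#' @param tab dose-response data.frame.
#' @export
write_dose_response <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
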