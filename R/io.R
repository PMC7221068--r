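#' Write / read peak sets in narrowPeak (BED6+4) format
#'
#' Scores are written to column 5 (rounded to integers, as in the format
#' spec) and duplicated into `signalValue`; `pValue`/`qValue` are `-1`
#' (unavailable) and the summit offset is the interval midpoint.
#'
#' @param peaks A [peak_set].
#' @param path Output file.
#' @return `path` (write) or a [peak_set] (read).
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$name, score = round(peaks$score), strand = ".",
    signalValue = peaks$score, pValue = -1, qValue = -1,
    peak = floor((peaks$end - peaks$start) / 2))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_narrowpeak
#' @param provenance Provenance label attached to the returned set.
#' @export
read_narrowpeak <- function(path, provenance = NA_character_) {
  gr <- rtracklayer::import(
    path, format = "BED",
    extraCols = c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric", peak = "integer"))
  peak_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
           score = gr$signalValue, name = gr$name, provenance = provenance)
}

#' Write / read coverage tracks in bedGraph format
#'
#' @param coverage `data.frame(chrom, start, end, value)`, 0-based half-open.
#' @param path File path.
#' @return `path` (write) or the coverage `data.frame` (read).
#' @export
write_bedgraph <- function(coverage, path) {
  write.table(coverage[, c("chrom", "start", "end", "value")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = gr$score, stringsAsFactors = FALSE)
}

#' Write a BED file (intervals only)
#'
#' @param df `data.frame` with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `name`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(df)) cols <- c(cols, "name")
  write.table(df[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  if ("name" %in% names(S4Vectors::mcols(gr))) out$name <- gr$name
  out
}

#' Write a crossmap statistics report as TSV
#'
#' @param stats A `crossmap_stats` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_crossmap_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a contrast result as TSV
#'
#' Columns: gene, base_mean, l2fc, se, p, padj, called, direction.
#'
#' @param result A `contrast_result` with `padj`.
#' @param path Output file.
#' @param l2fc_min,padj_max Thresholds used for the `called` column.
#' @param header Optional comment lines (prefixed `#`) written above the
#'   table, e.g. reproducibility metadata.
#' @return `path`, invisibly.
#' @export
write_contrast_result <- function(result, path, l2fc_min = 1.5,
                                  padj_max = 0.01, header = NULL) {
  called <- !is.na(result$padj) & abs(result$l2fc) > l2fc_min &
    result$padj < padj_max
  df <- data.frame(gene = result$gene,
                   base_mean = signif(result$base_mean, 6),
                   l2fc = signif(result$l2fc, 6),
                   se = signif(result$se, 6), p = signif(result$p, 6),
                   padj = signif(result$padj, 6), called = called,
                   direction = ifelse(called, sign(result$l2fc), 0))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
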