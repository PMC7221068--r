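#' Construct a count table
#'
#' A `count_table` bundles a genes x samples matrix of non-negative integer
#' counts with per-sample metadata and a genes x samples matrix of gene (or
#' allele) lengths. Hybrid allele columns come in A/B pairs drawn from the same
#' sequencing library, recorded in `samples$library`.
#'
#' @param counts Integer matrix, genes x samples, with row and column names.
#' @param samples `data.frame` with one row per column of `counts` and columns
#'   `sample`, `species` (`"A"`/`"B"`; for hybrid columns the sub-genome),
#'   `background` (`"parent"`/`"hybrid"`), `allele` (`"A"`/`"B"`/`NA`),
#'   `temperature` (`"warm"`/`"cold"`), `replicate` (integer), `library`
#'   (library identifier; shared by the two allele columns of one hybrid
#'   replicate).
#' @param gene_lengths Numeric matrix of bp lengths, same dimensions and
#'   dimnames as `counts`. Allele columns may differ in length per gene.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, samples, gene_lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have row (gene) and column (sample) names")
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be finite non-negative integers")
  }
  need <- c("sample", "species", "background", "allele", "temperature",
            "replicate", "library")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("samples is missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(counts)) {
    stop("samples must have one row per count column")
  }
  if (!identical(samples$sample, colnames(counts))) {
    stop("samples$sample must match colnames(counts)")
  }
  gene_lengths <- as.matrix(gene_lengths)
  if (!identical(dim(gene_lengths), dim(counts))) {
    stop("gene_lengths must match the dimensions of counts")
  }
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  # hybrid allele columns must pair up within a library
  hyb <- samples[samples$background == "hybrid", , drop = FALSE]
  if (nrow(hyb)) {
    per_lib <- table(hyb$library)
    if (any(per_lib != 2)) {
      stop("each hybrid library must contribute exactly one A and one B allele column")
    }
  }
  structure(
    list(counts = counts, samples = samples, gene_lengths = gene_lengths),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  backgrounds: ",
      paste(names(table(x$samples$background)), collapse = ", "), "\n",
      sep = "")
  cat("  temperatures: ",
      paste(names(table(x$samples$temperature)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Subset the columns of a count table
#'
#' @param x A `count_table`.
#' @param keep Logical or integer index over samples.
#' @return A `count_table` restricted to the selected samples.
#' @export
subset_samples <- function(x, keep) {
  stopifnot(inherits(x, "count_table"))
  count_table(
    x$counts[, keep, drop = FALSE],
    droplevels(x$samples[keep, , drop = FALSE]),
    x$gene_lengths[, keep, drop = FALSE]
  )
}

#' Write / read a count table as TSV
#'
#' The sample metadata is stored as a commented header block (`#meta` lines)
#' above the count matrix so a single file round-trips the whole object.
#' Lengths are stored as a parallel `#len` block only when they vary by
#' sample; otherwise a single `length` column is emitted.
#'
#' @param x A `count_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- x$samples
  for (col in names(meta)) {
    writeLines(paste0("#meta\t", col, "\t",
                      paste(as.character(meta[[col]]), collapse = "\t")), con)
  }
  df <- data.frame(gene = rownames(x$counts), x$counts, check.names = FALSE)
  writeLines(paste(names(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  ldf <- data.frame(gene = rownames(x$gene_lengths), x$gene_lengths,
                    check.names = FALSE)
  writeLines("#lengths", con)
  write.table(ldf, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#meta\t", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    meta[[parts[2]]] <- parts[-(1:2)]
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  meta$replicate <- as.integer(meta$replicate)
  meta$allele[meta$allele == "NA"] <- NA
  body_start <- length(meta_lines) + 1L
  len_at <- which(lines == "#lengths")
  header <- strsplit(lines[body_start], "\t", fixed = TRUE)[[1]]
  count_block <- lines[(body_start + 1L):(len_at - 1L)]
  cm <- do.call(rbind, strsplit(count_block, "\t", fixed = TRUE))
  counts <- matrix(as.numeric(cm[, -1, drop = FALSE]), nrow = nrow(cm),
                   dimnames = list(cm[, 1], header[-1]))
  lm_block <- lines[(len_at + 1L):length(lines)]
  lmx <- do.call(rbind, strsplit(lm_block, "\t", fixed = TRUE))
  lengths <- matrix(as.numeric(lmx[, -1, drop = FALSE]), nrow = nrow(lmx),
                    dimnames = list(lmx[, 1], header[-1]))
  count_table(counts, meta, lengths)
}
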