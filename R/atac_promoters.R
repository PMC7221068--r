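#' Define strand-aware promoter regions upstream of each gene
#'
#' For every gene the promoter is the upstream, non-genic interval abutting
#' the gene's 5' end on its strand, extending up to `max_len` bp (default 1
#' kb) and truncated earlier when a neighboring gene body or the chromosome
#' border is encountered — promoters therefore never overlap any annotated
#' gene body. Genes whose 5' end abuts a neighbor get a zero-length promoter,
#' emitted with `length = 0` so callers can exclude them from counting.
#'
#' @param annotation Annotation `data.frame` (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`; 1-based inclusive GTF coordinates, gene bodies assumed
#'   non-overlapping).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param max_len Maximum promoter length (default 1000).
#' @return `data.frame` of class `promoter_map`: `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), `length`, `reason`
#'   (`full_1kb`, `neighbor_gene`, `chromosome_border`).
#' @export
define_promoters <- function(annotation, chrom_lengths, max_len = 1000) {
  ann <- annotation[order(annotation$chrom, annotation$start), , drop = FALSE]
  # gene bodies, 0-based half-open
  gs <- ann$start - 1L
  ge <- ann$end
  n <- nrow(ann)
  p_start <- integer(n); p_end <- integer(n); reason <- character(n)
  for (i in seq_len(n)) {
    same <- which(ann$chrom == ann$chrom[i])
    same <- setdiff(same, i)
    clen <- chrom_lengths[[ann$chrom[i]]]
    if (ann$strand[i] == "+") {
      anchor <- gs[i]
      lo_gene <- suppressWarnings(max(ge[same][ge[same] <= anchor]))
      lo_gene <- if (is.finite(lo_gene)) lo_gene else 0L
      lo <- max(anchor - max_len, 0L, lo_gene)
      p_start[i] <- lo; p_end[i] <- anchor
      reason[i] <- if (anchor - lo == max_len) "full_1kb"
        else if (lo == lo_gene && lo_gene > max(anchor - max_len, 0L))
          "neighbor_gene"
        else if (lo == 0L && anchor < max_len) "chromosome_border"
        else "neighbor_gene"
    } else {
      anchor <- ge[i]
      hi_gene <- suppressWarnings(min(gs[same][gs[same] >= anchor]))
      hi_gene <- if (is.finite(hi_gene)) hi_gene else clen
      hi <- min(anchor + max_len, clen, hi_gene)
      p_start[i] <- anchor; p_end[i] <- hi
      reason[i] <- if (hi - anchor == max_len) "full_1kb"
        else if (hi == hi_gene && hi_gene < min(anchor + max_len, clen))
          "neighbor_gene"
        else if (hi == clen && clen - anchor < max_len) "chromosome_border"
        else "neighbor_gene"
    }
  }
  out <- data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
                    strand = ann$strand, start = p_start, end = p_end,
                    length = p_end - p_start, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("promoter_map", "data.frame")
  rownames(out) <- NULL
  out
}

#' Sum coverage over promoter regions
#'
#' The per-promoter sum of per-base coverage is the read-count proxy used for
#' promoter-level accessibility testing (real fragment counting needs BAMs,
#' which are out of scope; real-mode users can supply read counts directly).
#'
#' @param coverage `data.frame(chrom, start, end, value)`, 0-based half-open,
#'   non-negative values.
#' @param promoters A `promoter_map` (or any `data.frame` with `chrom`,
#'   `start`, `end`).
#' @return Numeric vector of coverage sums, one per promoter row (named by
#'   `gene_id` when present).
#' @export
promoter_counts <- function(coverage, promoters) {
  if (nrow(coverage) && any(coverage$value < 0)) {
    stop("coverage must be non-negative")
  }
  miss <- setdiff(unique(promoters$chrom), unique(coverage$chrom))
  if (nrow(coverage) && length(miss) == length(unique(promoters$chrom))) {
    stop("promoter chromosomes absent from coverage")
  }
  out <- numeric(nrow(promoters))
  if (nrow(coverage)) {
    pg <- GenomicRanges::GRanges(
      promoters$chrom,
      IRanges::IRanges(start = promoters$start + 1L, end = promoters$end))
    cg <- GenomicRanges::GRanges(
      coverage$chrom,
      IRanges::IRanges(start = coverage$start + 1L, end = coverage$end))
    hits <- GenomicRanges::findOverlaps(pg, cg)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ov <- IRanges::pintersect(IRanges::ranges(pg)[qh],
                                IRanges::ranges(cg)[sh])
      contrib <- IRanges::width(ov) * coverage$value[sh]
      agg <- tapply(contrib, qh, sum)
      out[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  if ("gene_id" %in% names(promoters)) names(out) <- promoters$gene_id
  out
}

#' Differential accessibility of homeologous promoter pairs
#'
#' Reuses the NB engine on promoter-level counts, controlling for the length
#' of the regions with allele-length-style normalization factors built from
#' promoter lengths (times per-sample size factors for library depth). Calls
#' use the liberal chromatin thresholds `|l2fc| > 1` (strict) and
#' `padj < 0.01`.
#'
#' @param counts Region x sample count matrix; columns belong to the two
#'   sub-genomes of the hybrid (e.g. 3 replicates each).
#' @param lengths Region x sample matrix of promoter lengths.
#' @param group Factor per column giving the sub-genome (`"A"`/`"B"`).
#' @param numerator,denominator Sign convention (default `log2(B/A)`, i.e.
#'   positive = more open in the B sub-genome).
#' @param l2fc_min,padj_max Calling thresholds (defaults 1, 0.01).
#' @param shrink Dispersion shrinkage weight.
#' @return List with `result` (per-region tests incl. `padj`), `more_open`
#'   and `less_open` (called regions, numerator side and denominator side).
#' @export
differential_accessibility <- function(counts, lengths, group,
                                       numerator = "B", denominator = "A",
                                       l2fc_min = 1, padj_max = 0.01,
                                       shrink = 0.5) {
  counts <- round(as.matrix(counts))
  if (!identical(dim(counts), dim(as.matrix(lengths)))) {
    stop("counts and lengths must have matching dimensions")
  }
  if (any(is.na(counts))) stop("missing counts for a pair member")
  lf <- allele_length_factors(lengths)
  sf <- size_factors(pmax(counts, 0) / lf)
  nf <- sweep(lf, 2, sf, `*`)
  alpha <- estimate_dispersion(counts, nf, group, shrink = shrink)
  res <- nb_wald(counts, group, nf, alpha, numerator, denominator)
  res$padj <- adjust_bh(res$p)
  calls <- call_de(res, l2fc_min, padj_max)
  list(result = res,
       more_open = calls[calls$direction == 1L, , drop = FALSE],
       less_open = calls[calls$direction == -1L, , drop = FALSE])
}

#' Link peaks to nearby genes through promoter overlap
#'
#' A peak is linked to a gene when the peak overlaps the gene's promoter
#' (>= 1 bp) AND the peak-to-gene-body distance is at most `max_dist` (1 kb).
#' For each strand the nearest qualifying gene is kept, so a peak between
#' divergent genes links to both. Peaks with no qualifying gene are reported
#' unlinked (`NA` gene).
#'
#' @param peaks A [peak_set].
#' @param annotation Gene annotation (1-based inclusive).
#' @param promoters `promoter_map` for the same annotation.
#' @param max_dist Maximum peak-to-gene distance (default 1000).
#' @return `data.frame(peak, gene_id, strand, distance)`; unlinked peaks have
#'   `NA` gene.
#' @export
assign_peaks_to_genes <- function(peaks, annotation, promoters,
                                  max_dist = 1000) {
  pg <- peaks_to_granges(peaks)
  prom <- promoters[promoters$length > 0, , drop = FALSE]
  prg <- GenomicRanges::GRanges(
    prom$chrom, IRanges::IRanges(prom$start + 1L, prom$end))
  ann_idx <- match(prom$gene_id, annotation$gene_id)
  gene_gr <- GenomicRanges::GRanges(
    annotation$chrom[ann_idx],
    IRanges::IRanges(annotation$start[ann_idx], annotation$end[ann_idx]))

  hits <- GenomicRanges::findOverlaps(pg, prg)
  links <- data.frame(peak = character(0), gene_id = character(0),
                      strand = character(0), distance = integer(0),
                      stringsAsFactors = FALSE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    dist <- GenomicRanges::distance(pg[qh], gene_gr[sh])
    ok <- !is.na(dist) & dist <= max_dist
    links <- data.frame(peak = pg$name[qh][ok],
                        gene_id = prom$gene_id[sh][ok],
                        strand = prom$strand[sh][ok],
                        distance = as.integer(dist[ok]),
                        stringsAsFactors = FALSE)
    # nearest qualifying gene per peak and strand
    links <- links[order(links$peak, links$strand, links$distance), ,
                   drop = FALSE]
    links <- links[!duplicated(links[, c("peak", "strand")]), , drop = FALSE]
  }
  unlinked <- setdiff(peaks$name, links$peak)
  if (length(unlinked)) {
    links <- rbind(links, data.frame(
      peak = unlinked, gene_id = NA_character_, strand = NA_character_,
      distance = NA_integer_, stringsAsFactors = FALSE))
  }
  rownames(links) <- NULL
  links
}

#' Integrate chromatin accessibility calls with expression results
#'
#' Joins background-specific peaks (or differentially accessible regions),
#' already linked to genes, with a differential-expression contrast and
#' summarizes concordance: how many linked genes are DE in the same
#' direction as the accessibility change, in the opposite direction, or not
#' DE at all.
#'
#' @param links `data.frame` with `gene_id` and `access_direction` (`1` =
#'   more accessible on the numerator side of the expression contrast, `-1`
#'   otherwise); typically built from [assign_peaks_to_genes()] output or
#'   [differential_accessibility()] calls.
#' @param de Called DE genes (`data.frame` with `gene`, `direction`).
#' @return List with `table` (the joined rows and their DE status) and
#'   `concordance` (named counts: `same_direction`, `opposite_direction`,
#'   `no_de`, `unmatched`).
#' @export
integrate_expression <- function(links, de) {
  if (nrow(links) == 0) {
    return(list(table = data.frame(), concordance = c(
      same_direction = 0L, opposite_direction = 0L, no_de = 0L,
      unmatched = 0L)))
  }
  de_dir <- setNames(de$direction, de$gene)
  matched <- links$gene_id %in% names(de_dir)
  known <- !is.na(links$gene_id)
  status <- rep("no_de", nrow(links))
  status[!known] <- "unmatched"
  dd <- de_dir[links$gene_id[matched]]
  status[matched] <- ifelse(dd == links$access_direction[matched],
                            "same_direction", "opposite_direction")
  out <- cbind(links, de_direction = ifelse(matched,
                                            de_dir[links$gene_id], NA),
               status = status)
  conc <- c(same_direction = sum(status == "same_direction"),
            opposite_direction = sum(status == "opposite_direction"),
            no_de = sum(status == "no_de" & known),
            unmatched = sum(status == "unmatched"))
  list(table = out, concordance = conc)
}
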