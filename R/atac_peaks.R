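#' Create a peak set
#'
#' Peaks are stored as a plain `data.frame` in BED conventions: 0-based,
#' half-open intervals with a `score` column (the narrowPeak column-5 score)
#' and a provenance label (replicate / biological condition).
#'
#' @param chrom,start,end,score Vectors describing the intervals (0-based
#'   half-open).
#' @param name Optional peak names (default `peak_1`, ...).
#' @param provenance Single label recorded on the set.
#' @return A `data.frame` of class `peak_set`, sorted by (chrom, start).
#' @export
peak_set <- function(chrom, start, end, score = 0,
                     name = NULL, provenance = NA_character_) {
  if (any(start < 0)) stop("negative coordinates")
  if (any(end <= start)) stop("peak starts must be < ends")
  if (is.null(name)) name <- sprintf("peak_%d", seq_along(chrom))
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), name = name,
                   score = as.numeric(score), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("peak_set", "data.frame")
  df
}

# peak_set (0-based half-open) -> GRanges (1-based inclusive)
peaks_to_granges <- function(p) {
  GenomicRanges::GRanges(
    seqnames = p$chrom,
    ranges = IRanges::IRanges(start = p$start + 1L, end = p$end),
    score = p$score, name = p$name)
}

# GRanges -> peak_set
granges_to_peaks <- function(gr, provenance = NA_character_) {
  score <- if ("score" %in% names(S4Vectors::mcols(gr))) gr$score else 0
  name <- if ("name" %in% names(S4Vectors::mcols(gr))) gr$name else NULL
  peak_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
           score = score, name = name, provenance = provenance)
}

#' Consensus peaks across replicates
#'
#' Overlapping replicate peaks (>= 1 shared base) are merged into their union
#' extent; a merged peak is kept if it is supported by at least `min_reps`
#' distinct replicates, and its score is the mean of the supporting peak
#' scores. This mirrors occupancy analysis, where the per-condition peak set
#' is the replicate-supported consensus.
#'
#' @param replicates List of `peak_set` objects (one per replicate).
#' @param min_reps Minimum number of distinct supporting replicates.
#' @return A consensus `peak_set`.
#' @export
replicate_consensus <- function(replicates, min_reps = 2) {
  if (min_reps > length(replicates)) {
    stop("min_reps exceeds the number of replicate peak sets")
  }
  grl <- lapply(replicates, peaks_to_granges)
  for (i in seq_along(grl)) grl[[i]]$rep <- i
  all_gr <- do.call(c, grl)
  merged <- GenomicRanges::reduce(all_gr)
  hits <- GenomicRanges::findOverlaps(merged, all_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  support <- vapply(split(all_gr$rep[sh], qh), function(r)
    length(unique(r)), integer(1))
  score <- vapply(split(all_gr$score[sh], qh), mean, numeric(1))
  keep_idx <- as.integer(names(support))[support >= min_reps]
  out <- merged[keep_idx]
  out$score <- score[as.character(keep_idx)]
  out$name <- sprintf("consensus_%d", seq_along(out))
  granges_to_peaks(out, provenance = "consensus")
}

#' Partition two peak sets into consensus and condition-specific peaks
#'
#' A peak from the parental set is "consensus" if it overlaps (>= 1 bp) any
#' peak of the hybrid sub-genome set, otherwise parent-specific; and
#' symmetrically for the hybrid side. Counts are reported from each side, so
#' `consensus_from_parent + parent_specific = |parent|`.
#'
#' @param parent,hybrid `peak_set` objects on the same chromosome namespace.
#' @return List with `consensus_from_parent`, `parent_specific`,
#'   `consensus_from_hybrid`, `hybrid_specific` (peak sets) and `counts`
#'   (named integer vector, including the totals).
#' @export
partition_peaksets <- function(parent, hybrid) {
  shared_chroms <- intersect(unique(parent$chrom), unique(hybrid$chrom))
  if (length(shared_chroms) == 0 && nrow(parent) && nrow(hybrid)) {
    stop("peak sets share no chromosome names")
  }
  pg <- peaks_to_granges(parent)
  hg <- peaks_to_granges(hybrid)
  p_hit <- GenomicRanges::countOverlaps(pg, hg) > 0
  h_hit <- GenomicRanges::countOverlaps(hg, pg) > 0
  out <- list(
    consensus_from_parent = parent[p_hit, , drop = FALSE],
    parent_specific = parent[!p_hit, , drop = FALSE],
    consensus_from_hybrid = hybrid[h_hit, , drop = FALSE],
    hybrid_specific = hybrid[!h_hit, , drop = FALSE]
  )
  out$counts <- c(
    parent = nrow(parent),
    consensus_from_parent = sum(p_hit),
    parent_specific = sum(!p_hit),
    hybrid = nrow(hybrid),
    consensus_from_hybrid = sum(h_hit),
    hybrid_specific = sum(!h_hit)
  )
  out
}

#' Estimate the fraction of shared peak loci from a partition
#'
#' The number of shared loci is taken as the mean of the consensus counts
#' seen from the two sides (they differ only when one peak overlaps several);
#' the locus universe adds the two specific partitions.
#'
#' @param counts The `counts` vector from [partition_peaksets()].
#' @return Estimated shared fraction in `[0, 1]`.
#' @export
estimate_shared_fraction <- function(counts) {
  shared <- (counts[["consensus_from_parent"]] +
               counts[["consensus_from_hybrid"]]) / 2
  unname(shared / (shared + counts[["parent_specific"]] +
                     counts[["hybrid_specific"]]))
}

#' Compare peak-score distributions between partition groups
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum tests on every pair of groups,
#' using the normal approximation with tie and continuity correction. Used to
#' ask whether condition-specific peaks score systematically lower than
#' consensus peaks.
#'
#' @param groups Named list of numeric score vectors (each non-empty).
#' @return `data.frame(group1, group2, n1, n2, p_value)`.
#' @export
score_comparison <- function(groups) {
  if (any(lengths(groups) == 0)) stop("all score groups must be non-empty")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    p <- suppressWarnings(
      wilcox.test(groups[[i]], groups[[j]], alternative = "two.sided",
                  exact = FALSE, correct = TRUE)$p.value)
    data.frame(group1 = nm[i], group2 = nm[j],
               n1 = length(groups[[i]]), n2 = length(groups[[j]]),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Mask genomic regions with N
#'
#' Replaces every base inside the given BED-style regions (0-based half-open)
#' with `N`, leaving everything else unchanged. Used to neutralize repetitive
#' loci (e.g. rDNA arrays) that would otherwise dominate coverage.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param regions `data.frame(chrom, start, end)`, 0-based half-open.
#' @return The masked genome (named character vector).
#' @export
mask_regions <- function(genome, regions) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (nrow(regions) == 0) return(genome)
  if (!all(regions$chrom %in% names(genome))) {
    stop("region chromosome absent from genome")
  }
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    s <- regions$start[i]
    e <- regions$end[i]
    if (s < 0 || e > nchar(genome[[chrom]]) || e <= s) {
      stop("region out of chromosome bounds: ", chrom, ":", s, "-", e)
    }
    substr(genome[[chrom]], s + 1L, e) <- strrep("N", e - s)
  }
  genome
}
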