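#' Simulate replicate ATAC peak sets and coverage for two backgrounds
#'
#' Peaks are centered on a random subset of promoters. A `shared_fraction` of
#' peaks is present in both backgrounds (parent and hybrid sub-genome); the
#' remainder is split evenly into parent-specific and hybrid-specific peaks.
#' Background-specific peaks draw lower scores on average than shared peaks,
#' emulating the empirical observation that condition-specific peaks tend to
#' be weaker calls. Replicate peak sets are jittered copies of the background
#' truth (bounded coordinate noise, multiplicative score noise). Coverage
#' tracks are piecewise-constant and consistent with peak placement.
#'
#' @param promoters Promoter map (`data.frame` with `chrom`, `start`, `end`,
#'   0-based half-open), e.g. from [define_promoters()]. One promoter hosts at
#'   most one peak, so `n_peaks` must not exceed the number of usable
#'   promoters.
#' @param n_peaks Total number of distinct peak loci.
#' @param shared_fraction Fraction of peak loci present in both backgrounds.
#' @param n_reps Replicates per background.
#' @param peak_width Peak width in bp.
#' @param jitter Maximum absolute coordinate noise per replicate (bp);
#'   `jitter = 0` disables all replicate noise (score noise included), making
#'   replicate sets identical.
#' @param score_jitter Log-sd of the multiplicative replicate score noise.
#' @param score_shared,score_specific Mean scores of shared and
#'   background-specific peaks (normal draws, sd `score_sd`, truncated at 50).
#' @param score_sd Score standard deviation.
#' @param seed Integer seed.
#' @return List with `parent`, `hybrid` (each a list of `n_reps` replicate
#'   [peak_set]s), `truth` (`data.frame` of peak loci and their status),
#'   `coverage` (per background, 0-based half-open
#'   `data.frame(chrom, start, end, value)`), and `params`.
#' @export
simulate_atac <- function(promoters, n_peaks = 1000, shared_fraction = 0.88,
                          n_reps = 3, peak_width = 300, jitter = 20,
                          score_shared = 600, score_specific = 350,
                          score_sd = 120, score_jitter = 0.05, seed = 1) {
  check_fraction(shared_fraction, "shared_fraction")
  usable <- promoters[(promoters$end - promoters$start) >= 1, , drop = FALSE]
  if (n_peaks > nrow(usable)) {
    stop("n_peaks exceeds the number of usable promoters (", nrow(usable), ")")
  }
  set.seed(seed)

  loci <- usable[sample.int(nrow(usable), n_peaks), , drop = FALSE]
  center <- floor((loci$start + loci$end) / 2)
  half <- floor(peak_width / 2)
  start <- pmax(center - half, 0L)
  end <- start + peak_width

  n_shared <- round(shared_fraction * n_peaks)
  n_spec <- n_peaks - n_shared
  n_par <- ceiling(n_spec / 2)
  status <- sample(c(rep("shared", n_shared),
                     rep("parent_specific", n_par),
                     rep("hybrid_specific", n_spec - n_par)))
  base_score <- ifelse(status == "shared",
                       rnorm(n_peaks, score_shared, score_sd),
                       rnorm(n_peaks, score_specific, score_sd))
  base_score <- pmax(base_score, 50)

  truth <- data.frame(
    locus = sprintf("locus_%04d", seq_len(n_peaks)),
    chrom = loci$chrom, start = start, end = end,
    status = status, score = base_score, stringsAsFactors = FALSE)

  jittered_set <- function(rows, rep_i, label) {
    k <- nrow(rows)
    dj <- if (jitter > 0) sample(seq(-jitter, jitter), k, replace = TRUE) else 0L
    sc <- if (jitter > 0) rows$score * exp(rnorm(k, 0, score_jitter)) else rows$score
    peak_set(rows$chrom, pmax(rows$start + dj, 0L), rows$end + dj,
             score = sc, name = rows$locus,
             provenance = sprintf("%s_rep%d", label, rep_i))
  }

  par_rows <- truth[truth$status %in% c("shared", "parent_specific"), ]
  hyb_rows <- truth[truth$status %in% c("shared", "hybrid_specific"), ]
  parent <- lapply(seq_len(n_reps), function(r)
    jittered_set(par_rows, r, "parent"))
  hybrid <- lapply(seq_len(n_reps), function(r)
    jittered_set(hyb_rows, r, "hybrid"))

  coverage <- list(
    parent = peaks_to_coverage(peak_set(par_rows$chrom, par_rows$start,
                                        par_rows$end, par_rows$score)),
    hybrid = peaks_to_coverage(peak_set(hyb_rows$chrom, hyb_rows$start,
                                        hyb_rows$end, hyb_rows$score))
  )

  list(parent = parent, hybrid = hybrid, truth = truth, coverage = coverage,
       params = list(n_peaks = n_peaks, shared_fraction = shared_fraction,
                     n_reps = n_reps, peak_width = peak_width,
                     jitter = jitter, seed = seed))
}

#' Piecewise-constant coverage implied by a peak set
#'
#' Each peak contributes `score / width` uniformly over its interval;
#' overlapping contributions add. Intervals are emitted 0-based half-open,
#' sorted, bedGraph-ready.
#'
#' @param peaks A [peak_set].
#' @return `data.frame(chrom, start, end, value)`.
#' @export
peaks_to_coverage <- function(peaks) {
  if (nrow(peaks) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  }
  gr <- peaks_to_granges(peaks)
  per_base <- peaks$score / (peaks$end - peaks$start)
  dj <- GenomicRanges::disjoin(gr)
  hits <- GenomicRanges::findOverlaps(dj, gr)
  val <- vapply(split(per_base[S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits)), sum, numeric(1))
  keep <- as.integer(names(val))
  out <- dj[keep]
  data.frame(chrom = as.character(GenomicRanges::seqnames(out)),
             start = GenomicRanges::start(out) - 1L,
             end = GenomicRanges::end(out),
             value = as.numeric(val), stringsAsFactors = FALSE)
}
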