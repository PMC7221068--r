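#' Median-of-ratios size factors
#'
#' Classic library-size estimation for count matrices: each sample's factor is
#' the median across genes of the ratio of its count to the per-gene geometric
#' mean, computed over genes with positive counts in every sample. Factors are
#' rescaled to geometric mean 1 so normalized counts stay on the counting
#' scale.
#'
#' @param counts Genes x samples count matrix.
#' @return Positive numeric vector of per-sample size factors (geometric
#'   mean 1).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no gene has positive counts in all samples")
  }
  log_gm <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  sf <- apply(counts[all_pos, , drop = FALSE], 2, function(col)
    exp(median(log(col) - log_gm)))
  sf <- sf / geomean(sf)
  sf
}

#' Allele length normalization factors
#'
#' Within-hybrid allele-specific comparisons must correct for ortholog length
#' differences but NOT for library size, because the two allele columns of a
#' replicate come from the same library. The factor for gene g in sample s is
#' `length[g, s] / geomean_s(length[g, ])`, i.e. the length matrix divided by
#' its per-gene (row) geometric mean — so for every gene the factors multiply
#' to 1 across samples and carry no library-size component.
#'
#' @param lengths Genes x samples matrix of positive bp lengths.
#' @return Normalization-factor matrix of the same shape, per-gene geometric
#'   mean exactly 1.
#' @export
allele_length_factors <- function(lengths) {
  lengths <- as.matrix(lengths)
  if (any(lengths <= 0)) stop("lengths must be strictly positive")
  lengths / exp(rowMeans(log(lengths)))
}

#' Combined length and library normalization factors
#'
#' For between-species comparisons, where ortholog lengths differ AND samples
#' come from different libraries: the element-wise product of the allele
#' length factors and per-sample median-of-ratios size factors computed on
#' length-corrected counts.
#'
#' @param lengths Genes x samples matrix of positive bp lengths.
#' @param counts Genes x samples count matrix (same shape).
#' @return Normalization-factor matrix.
#' @export
length_and_library_factors <- function(lengths, counts) {
  lf <- allele_length_factors(lengths)
  corrected <- as.matrix(counts) / lf
  sf <- size_factors(corrected)
  sweep(lf, 2, sf, `*`)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure with monotonicity enforcement; `NA` p-values are left out
#' of the multiplicity count and returned as `NA`.
#'
#' @param p Vector of p-values in `[0, 1]` (NAs allowed).
#' @return Vector of adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)
  ord <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * pv[ord]))
  out[ok[ord]] <- adj
  out
}

#' Call differentially expressed genes at the headline thresholds
#'
#' A gene is called when `|l2fc| > l2fc_min` AND `padj < padj_max`, both
#' strict inequalities (a gene at exactly the fold-change threshold is not
#' called). Optionally an expression floor on the mean normalized count can
#' be applied (relaxed-filter variant).
#'
#' @param result A contrast result `data.frame` with columns `gene`, `l2fc`,
#'   `padj` (and `base_mean` if `base_mean_min` is used).
#' @param l2fc_min Absolute log2-fold-change threshold (default 1.5).
#' @param padj_max Adjusted-p threshold (default 0.01).
#' @param base_mean_min Optional minimum mean normalized expression.
#' @return `data.frame(gene, l2fc, padj, direction)` of called genes;
#'   `direction` is `1` (numerator higher) or `-1`.
#' @export
call_de <- function(result, l2fc_min = 1.5, padj_max = 0.01,
                    base_mean_min = NULL) {
  if (!"padj" %in% names(result)) stop("result must carry padj")
  hit <- !is.na(result$padj) & !is.na(result$l2fc) &
    abs(result$l2fc) > l2fc_min & result$padj < padj_max
  if (!is.null(base_mean_min)) {
    hit <- hit & result$base_mean > base_mean_min
  }
  out <- result[hit, c("gene", "l2fc", "padj"), drop = FALSE]
  out$direction <- ifelse(out$l2fc > 0, 1L, -1L)
  rownames(out) <- NULL
  out
}
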