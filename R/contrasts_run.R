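#' Specify one contrast of the four-way design
#'
#' The four contrast families mirror the experimental design of a hybrid and
#' its two parents profiled at two temperatures:
#'
#' * `parents`: species A parent vs species B parent (`l2fc = log2(A/B)`),
#'   length-and-library normalization (ortholog lengths differ);
#' * `backgrounds`: hybrid sub-genome vs the matching parent
#'   (`l2fc = log2(hybrid/parent)`), length-and-library normalization;
#' * `homeologs`: allele A vs allele B within hybrid libraries
#'   (`l2fc = log2(alleleA/alleleB)`), allele-length-only normalization (the
#'   two allele columns of a replicate come from the same library, so library
#'   size must NOT be corrected);
#' * `temperature`: cold vs warm within one species/background
#'   (`l2fc = log2(cold/warm)`).
#'
#' @param family One of `"parents"`, `"backgrounds"`, `"homeologs"`,
#'   `"temperature"`.
#' @param species Species selector (`"A"`/`"B"`), required for `backgrounds`
#'   and `temperature`.
#' @param background Background selector for `temperature` contrasts
#'   (default `"parent"`).
#' @param temperature Temperature selector (`"warm"`/`"cold"`), required for
#'   all families except `temperature`.
#' @return A `contrast_spec` list.
#' @export
contrast_spec <- function(family, species = NULL, background = "parent",
                          temperature = NULL) {
  family <- match.arg(family,
                      c("parents", "backgrounds", "homeologs", "temperature"))
  if (family %in% c("parents", "backgrounds", "homeologs") &&
      is.null(temperature)) {
    stop("family '", family, "' needs a temperature selector")
  }
  if (family %in% c("backgrounds", "temperature") && is.null(species)) {
    stop("family '", family, "' needs a species selector")
  }
  structure(list(family = family, species = species,
                 background = background, temperature = temperature),
            class = "contrast_spec")
}

#' Run one contrast of the four-way design
#'
#' Selects the samples named by the spec, applies the normalization regime
#' fixed by the contrast family, estimates per-gene dispersions, runs the NB
#' Wald test, adjusts p-values (BH) and calls genes at the given thresholds.
#'
#' @param table A [count_table].
#' @param spec A [contrast_spec].
#' @param l2fc_min,padj_max Calling thresholds (defaults 1.5 and 0.01, strict
#'   inequalities).
#' @param shrink Dispersion shrinkage weight (see [estimate_dispersion()]).
#' @return List with `result` (per-gene `contrast_result` incl. `padj`),
#'   `de` (called genes with directions), `spec`, and `n_samples`.
#' @export
run_contrast <- function(table, spec, l2fc_min = 1.5, padj_max = 0.01,
                         shrink = 0.5) {
  stopifnot(inherits(table, "count_table"), inherits(spec, "contrast_spec"))
  s <- table$samples
  fam <- spec$family
  if (fam == "parents") {
    keep <- s$background == "parent" & s$temperature == spec$temperature
    group <- s$species[keep]; numerator <- "A"; denominator <- "B"
    mode <- "length_and_library"
  } else if (fam == "homeologs") {
    keep <- s$background == "hybrid" & s$temperature == spec$temperature
    group <- s$allele[keep]; numerator <- "A"; denominator <- "B"
    mode <- "allele_length_only"
  } else if (fam == "backgrounds") {
    keep <- s$species == spec$species & s$temperature == spec$temperature &
      (s$background == "parent" |
         (s$background == "hybrid" & s$allele == spec$species))
    group <- s$background[keep]; numerator <- "hybrid"
    denominator <- "parent"
    mode <- "length_and_library"
  } else {
    keep <- s$species == spec$species & s$background == spec$background &
      (spec$background == "parent" | s$allele == spec$species)
    group <- s$temperature[keep]; numerator <- "cold"
    denominator <- "warm"
    mode <- "length_and_library"
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("contrast selects no samples")
  counts <- table$counts[, keep, drop = FALSE]
  lengths <- table$gene_lengths[, keep, drop = FALSE]
  if (length(unique(group)) < 2) stop("contrast selects a single group")

  nf <- switch(mode,
    allele_length_only = allele_length_factors(lengths),
    length_and_library = length_and_library_factors(lengths, counts))
  alpha <- estimate_dispersion(counts, nf, group, shrink = shrink)
  res <- nb_wald(counts, group, nf, alpha, numerator, denominator)
  res$padj <- adjust_bh(res$p)
  de <- call_de(res, l2fc_min, padj_max)
  norm <- counts / nf
  group_means <- cbind(rowMeans(norm[, group == numerator, drop = FALSE]),
                       rowMeans(norm[, group == denominator, drop = FALSE]))
  colnames(group_means) <- c(numerator, denominator)
  list(result = res, de = de, spec = spec, n_samples = sum(keep),
       group_means = group_means)
}

#' Transcriptome distance as 1 - Spearman rho
#'
#' Rank correlation with average ranks for ties; the distance lies in
#' `[0, 2]`. A constant vector leaves the correlation undefined: the result
#' is `NA` with a warning.
#'
#' @param a,b Equal-length expression vectors (length >= 3).
#' @return `1 - rho`, or `NA` for degenerate input.
#' @export
expression_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (length(a) < 3) stop("need at least 3 observations")
  if (length(unique(a)) == 1 || length(unique(b)) == 1) {
    warning("constant expression vector: distance undefined")
    return(NA_real_)
  }
  1 - cor(a, b, method = "spearman")
}

#' Temperature-dependent allele-specific expression
#'
#' Tests, per gene, the allele x temperature interaction in an NB model over
#' the hybrid allele columns at both temperatures. The interaction
#' coefficient is the log2 change of the within-hybrid allelic ratio between
#' cold and warm; genes pass at `|l2fc| > l2fc_min` and `padj < padj_max`.
#' An interaction test is used instead of differencing per-temperature ASE
#' call sets because set differences conflate threshold noise with true
#' condition dependence.
#'
#' @param table A [count_table] with hybrid allele columns at both
#'   temperatures.
#' @param l2fc_min,padj_max Thresholds (defaults 1.5, 0.01).
#' @param shrink Dispersion shrinkage weight.
#' @return List with `result` (per-gene interaction tests incl. `padj`) and
#'   `de` (genes passing, with direction).
#' @export
temperature_dependent_ase <- function(table, l2fc_min = 1.5,
                                      padj_max = 0.01, shrink = 0.5) {
  stopifnot(inherits(table, "count_table"))
  s <- table$samples
  keep <- s$background == "hybrid"
  if (length(unique(s$temperature[keep])) < 2) {
    stop("hybrid allele counts are needed at both temperatures")
  }
  counts <- table$counts[, keep, drop = FALSE]
  lengths <- table$gene_lengths[, keep, drop = FALSE]
  sm <- s[keep, , drop = FALSE]

  # allele length factors x per-library size factors: alleles share their
  # replicate's library, so the library component is averaged within pairs
  lf <- allele_length_factors(lengths)
  sf <- size_factors(counts / lf)
  sf_lib <- ave(sf, sm$library)
  sf_lib <- sf_lib / geomean(sf_lib)
  nf <- sweep(lf, 2, sf_lib, `*`)

  is_a <- as.numeric(sm$allele == "A")
  is_cold <- as.numeric(sm$temperature == "cold")
  X <- cbind(intercept = 1, alleleA = is_a, cold = is_cold,
             alleleA_cold = is_a * is_cold)
  cell <- interaction(sm$allele, sm$temperature)
  alpha <- estimate_dispersion(counts, nf, cell, shrink = shrink)
  res <- nb_wald_coef(counts, X, "alleleA_cold", nf, alpha)
  res$padj <- adjust_bh(res$p)
  de <- call_de(res, l2fc_min, padj_max)
  list(result = res, de = de)
}
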