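#' Design per-gene effect structure for the four inheritance categories
#'
#' Each gene is assigned one of four categories describing how expression
#' differences behave across the parental and hybrid comparisons:
#'
#' * `inherited_ASE`: the parental difference persists between homeologs in
#'   the hybrid (`l2fc_parents` and `l2fc_homeologs` equal, same sign, both
#'   above the calling threshold);
#' * `acquired_ASE`: homeolog imbalance with no parental difference
#'   (`l2fc_parents = 0`);
#' * `attenuated`: a parental difference that disappears in the hybrid
#'   (`l2fc_homeologs = 0`);
#' * `conserved`: no designed effect in either comparison.
#'
#' Per-gene baseline means and NB dispersions are drawn log-uniformly; the
#' per-gene dispersion range (default `[0.01, 0.3]`) is a modeling choice, not
#' an empirical value. Ortholog/allele length pairs are drawn with a
#' log-uniform length ratio (default `[0.8, 1.25]`) so that length-aware
#' normalization is actually exercised.
#'
#' @param n_genes Number of genes.
#' @param fractions Named fractions for categories `conserved`,
#'   `inherited_ASE`, `attenuated`, `acquired_ASE`; must sum to 1.
#' @param effect Absolute designed log2 fold change for non-conserved genes.
#' @param baseline_range Log-uniform range for baseline means.
#' @param dispersion_range Log-uniform range for NB dispersion alpha
#'   (variance = mu + alpha mu^2).
#' @param length_ratio_range Log-uniform range for the ortholog length ratio
#'   len_A/len_B.
#' @param n_temp_ase Number of genes given a temperature x allele interaction
#'   (temperature-dependent ASE) of magnitude `temp_ase_effect`.
#' @param temp_ase_effect Interaction log2 effect.
#' @param temp_fraction Fraction of genes given a main temperature effect of
#'   magnitude `temp_effect`.
#' @param temp_effect Main temperature log2 effect (cold relative to warm).
#' @param gene_ids Optional gene identifiers (defaults to `g0001`, ...).
#' @param seed Integer seed.
#' @return `data.frame` with one row per gene: `gene_id`, `category`,
#'   `baseline_mean`, `l2fc_parents`, `l2fc_homeologs`, `l2fc_background`,
#'   `l2fc_temperature`, `l2fc_ase_temp`, `dispersion`, `len_A`, `len_B`.
#' @export
make_effect_design <- function(n_genes,
                               fractions = c(conserved = 0.88,
                                             inherited_ASE = 0.04,
                                             attenuated = 0.05,
                                             acquired_ASE = 0.03),
                               effect = 3,
                               baseline_range = c(500, 5000),
                               dispersion_range = c(0.01, 0.3),
                               length_ratio_range = c(0.8, 1.25),
                               n_temp_ase = 0,
                               temp_ase_effect = 3,
                               temp_fraction = 0,
                               temp_effect = 3,
                               gene_ids = NULL,
                               seed = 1) {
  cats <- c("conserved", "inherited_ASE", "attenuated", "acquired_ASE")
  if (!all(cats %in% names(fractions))) {
    stop("fractions must be named with: ", paste(cats, collapse = ", "))
  }
  fractions <- fractions[cats]
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  set.seed(seed)

  counts <- floor(fractions * n_genes)
  rem <- n_genes - sum(counts)
  if (rem > 0) {
    # hand leftovers to the largest fractional parts
    frac_part <- fractions * n_genes - counts
    ord <- order(frac_part, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  category <- sample(rep(cats, counts))

  sign_eff <- sample(c(-1, 1), n_genes, replace = TRUE)
  l2fc_parents <- ifelse(category %in% c("inherited_ASE", "attenuated"),
                         sign_eff * effect, 0)
  l2fc_homeologs <- ifelse(category == "inherited_ASE", sign_eff * effect,
                           ifelse(category == "acquired_ASE",
                                  sign_eff * effect, 0))

  l2fc_temperature <- numeric(n_genes)
  if (temp_fraction > 0) {
    idx <- sample.int(n_genes, round(temp_fraction * n_genes))
    l2fc_temperature[idx] <- sample(c(-1, 1), length(idx),
                                    replace = TRUE) * temp_effect
  }
  l2fc_ase_temp <- numeric(n_genes)
  if (n_temp_ase > 0) {
    idx <- sample.int(n_genes, n_temp_ase)
    l2fc_ase_temp[idx] <- sample(c(-1, 1), length(idx),
                                 replace = TRUE) * temp_ase_effect
  }

  len_geo <- runif_log(n_genes, 500, 2000)
  ratio <- runif_log(n_genes, length_ratio_range[1], length_ratio_range[2])
  len_A <- round(len_geo * sqrt(ratio))
  len_B <- round(len_geo / sqrt(ratio))

  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(n_genes))

  data.frame(
    gene_id = gene_ids,
    category = category,
    baseline_mean = runif_log(n_genes, baseline_range[1], baseline_range[2]),
    l2fc_parents = l2fc_parents,
    l2fc_homeologs = l2fc_homeologs,
    l2fc_background = 0,
    l2fc_temperature = l2fc_temperature,
    l2fc_ase_temp = l2fc_ase_temp,
    dispersion = runif_log(n_genes, dispersion_range[1], dispersion_range[2]),
    len_A = len_A,
    len_B = len_B,
    stringsAsFactors = FALSE
  )
}

# NB draw that degrades to Poisson where alpha == 0
rnbinom_safe <- function(mu, alpha) {
  out <- numeric(length(mu))
  pois <- alpha <= 0
  if (any(pois)) out[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / alpha[!pois])
  }
  out
}

#' Simulate a full-design count table from an effect design
#'
#' Emulates the four-way experimental design: diploid parents of species A and
#' B and their hybrid, in `n_reps` biological replicates at two temperatures.
#' Hybrid libraries contribute one column per allele (sub-genome); the two
#' allele columns of a replicate share its library depth factor. Each count is
#' drawn NB with
#' `mean = baseline * depth * length_factor * 2^(applicable designed effects)`
#' and the gene's dispersion. Designed log2 effects are split symmetrically
#' around the baseline (+e/2 vs -e/2) so that the corresponding contrast
#' recovers `e`. By default the hybrid inherits parental expression
#' (`l2fc_background = 0`). The length factor is `len/geomean(len_A, len_B)`:
#' longer copies attract proportionally more reads, which is what the
#' length-aware normalization modes must undo.
#'
#' @param design Effect design from [make_effect_design()].
#' @param n_reps Replicates per condition (default 3).
#' @param depth_factors Optional per-library depth scalars, in library order
#'   (parents A, parents B, hybrid; warm then cold). Default: log-uniform in
#'   `[0.7, 1.4]`.
#' @param temperatures Temperature levels to simulate (default both).
#' @param seed Integer seed; same seed, same matrix.
#' @return A [count_table].
#' @export
simulate_counts <- function(design, n_reps = 3, depth_factors = NULL,
                            temperatures = c("warm", "cold"), seed = 1) {
  if (any(design$baseline_mean <= 0)) stop("baseline means must be > 0")
  if (any(design$dispersion < 0)) stop("dispersions must be >= 0")
  set.seed(seed)

  g <- nrow(design)
  libs <- expand.grid(
    replicate = seq_len(n_reps),
    unit = c("parentA", "parentB", "hybrid"),
    temperature = temperatures,
    stringsAsFactors = FALSE
  )
  libs$library <- sprintf("lib_%s_%s_r%d", libs$unit, libs$temperature,
                          libs$replicate)
  if (is.null(depth_factors)) {
    depth_factors <- runif_log(nrow(libs), 0.7, 1.4)
  }
  if (length(depth_factors) != nrow(libs)) {
    stop("depth_factors must have one value per library (",
         nrow(libs), ")")
  }
  libs$depth <- depth_factors

  # expand libraries into sample columns (hybrid -> two allele columns)
  rows <- list()
  for (i in seq_len(nrow(libs))) {
    li <- libs[i, ]
    if (li$unit == "hybrid") {
      for (al in c("A", "B")) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sprintf("hyb.%s.%s.r%d", al, li$temperature, li$replicate),
          species = al, background = "hybrid", allele = al,
          temperature = li$temperature, replicate = li$replicate,
          library = li$library, depth = li$depth, stringsAsFactors = FALSE)
      }
    } else {
      sp <- if (li$unit == "parentA") "A" else "B"
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("%s.parent.%s.r%d", sp, li$temperature, li$replicate),
        species = sp, background = "parent", allele = NA_character_,
        temperature = li$temperature, replicate = li$replicate,
        library = li$library, depth = li$depth, stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, rows)

  len_geo <- sqrt(design$len_A * design$len_B)
  mu <- matrix(0, g, nrow(samples),
               dimnames = list(design$gene_id, samples$sample))
  lengths <- mu
  for (s in seq_len(nrow(samples))) {
    sm <- samples[s, ]
    len_s <- if (sm$species == "A") design$len_A else design$len_B
    eff <- numeric(g)
    if (sm$background == "parent") {
      eff <- eff + (if (sm$species == "A") 0.5 else -0.5) * design$l2fc_parents
    } else {
      eff <- eff + (if (sm$allele == "A") 0.5 else -0.5) * design$l2fc_homeologs
      eff <- eff + design$l2fc_background
    }
    if (sm$temperature == "cold") {
      eff <- eff + design$l2fc_temperature
      if (sm$background == "hybrid") {
        eff <- eff + (if (sm$allele == "A") 0.5 else -0.5) * design$l2fc_ase_temp
      }
    }
    mu[, s] <- design$baseline_mean * sm$depth * (len_s / len_geo) * 2^eff
    lengths[, s] <- len_s
  }

  counts <- matrix(
    rnbinom_safe(as.vector(mu), rep(design$dispersion, ncol(mu))),
    nrow = g, dimnames = dimnames(mu))
  samples$depth <- NULL
  count_table(counts, samples, lengths)
}
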