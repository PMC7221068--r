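# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no data files.

# evenly tiled single-chromosome annotation: every gene gets a clean upstream
# promoter of min(spacing - gene_len, 1000) bp
tiled_annotation <- function(n, spacing = 1500, gene_len = 500,
                             chrom = "chrT") {
  data.frame(
    gene_id = sprintf("t%04d", seq_len(n)),
    chrom = chrom,
    start = (seq_len(n) - 1L) * spacing + spacing - gene_len + 1L,
    end = (seq_len(n) - 1L) * spacing + spacing,
    strand = "+",
    stringsAsFactors = FALSE
  )
}

tiled_chrom_lengths <- function(n, spacing = 1500, chrom = "chrT") {
  setNames(n * spacing + 2000L, chrom)
}

# small cached genome pair so quant tests don't regenerate repeatedly
small_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_genome_pair(n_chrom = 1, chrom_len = 20000,
                                     n_genes = 30, divergence = 0.2,
                                     seed = 101)
    }
    cache
  }
})

# --- independent oracles ------------------------------------------------

# brute-force read assignment: scan both genomes (both strands) for every
# read k-mer with fixed-string matching; never touches the k-mer index
oracle_assign <- function(reads, genomes, k, min_margin = 1) {
  revcomp <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  hay <- list(
    A = c(genomes$sequences_A, revcomp(genomes$sequences_A)),
    B = c(genomes$sequences_B, revcomp(genomes$sequences_B))
  )
  vapply(unname(reads), function(rd) {
    n_k <- nchar(rd) - k + 1L
    kms <- substring(rd, seq_len(n_k), seq_len(n_k) + k - 1L)
    inA <- vapply(kms, function(km)
      any(vapply(hay$A, function(h) grepl(km, h, fixed = TRUE),
                 logical(1))), logical(1))
    inB <- vapply(kms, function(km)
      any(vapply(hay$B, function(h) grepl(km, h, fixed = TRUE),
                 logical(1))), logical(1))
    vA <- sum(inA & !inB)
    vB <- sum(inB & !inA)
    if (!any(inA | inB)) return("unassigned")
    if (vA == vB || abs(vA - vB) < min_margin) return("ambiguous")
    if (vA > vB) "genome_A" else "genome_B"
  }, character(1))
}

# per-base coverage sum over an interval, by explicit base enumeration
oracle_coverage_sum <- function(coverage, chrom, start, end) {
  total <- 0
  for (b in seq(start, end - 1L)) {
    sel <- coverage$chrom == chrom & coverage$start <= b & coverage$end > b
    total <- total + sum(coverage$value[sel])
  }
  total
}

# exact two-sided rank-sum p-value by exhaustive enumeration of group splits
oracle_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v)
  idx <- utils::combn(n, length(x))
  r <- rank(all_v)
  obs <- sum(r[seq_along(x)])
  stats_all <- apply(idx, 2, function(i) sum(r[i]))
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-12)
}

# quick NB count matrix for degene tests
sim_nb_matrix <- function(g, mu, alpha, n_per_group = 3, l2fc = 0,
                          n_affected = 0, seed = 1) {
  set.seed(seed)
  if (length(mu) == 1) mu <- rep(mu, g)
  eff <- c(rep(l2fc, n_affected), rep(0, g - n_affected)) *
    sample(c(-1, 1), g, replace = TRUE)
  muA <- mu * 2^(eff / 2)
  muB <- mu * 2^(-eff / 2)
  draw <- function(m) {
    if (alpha == 0) rpois(g * n_per_group, rep(m, n_per_group))
    else rnbinom(g * n_per_group, mu = rep(m, n_per_group), size = 1 / alpha)
  }
  cts <- cbind(matrix(draw(muA), g), matrix(draw(muB), g))
  rownames(cts) <- sprintf("g%04d", seq_len(g))
  colnames(cts) <- c(paste0("A_r", seq_len(n_per_group)),
                     paste0("B_r", seq_len(n_per_group)))
  list(counts = cts, group = rep(c("A", "B"), each = n_per_group),
       truth_l2fc = eff)
}
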