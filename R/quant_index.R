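# canonical form of a k-mer: lexicographic min of the k-mer and its reverse
# complement (k odd, so no k-mer is its own reverse complement)
canonical_kmers <- function(kmers) {
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  pmin(kmers, rc)
}

# enumerate canonical k-mers of one sequence with their 1-based positions
seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  starts <- seq_len(L - k + 1L)
  data.table::data.table(kmer = canonical_kmers(substring(seq, starts,
                                                          starts + k - 1L)),
                         pos = starts)
}

#' Build a k-mer index over a concatenated two-genome reference
#'
#' Every canonical k-mer of both sub-genomes is recorded with its occurrences
#' (sub-genome, chromosome, 1-based position), and classified as exclusive to
#' one sub-genome or shared. This index is the desk-scale stand-in for an
#' aligner index over a concatenated parental reference: read assignment then
#' reduces to counting exclusive k-mer votes.
#'
#' @param genomes Either the `genomes` list from [generate_genome_pair()] or a
#'   named list of genomes, each a named character vector of chromosomes.
#' @param k Odd k-mer size in `[11, 31]` (default 21).
#' @return A `kmer_index` object (list with `k`, `genome_names`, `occ`
#'   occurrence table, `class` k-mer classification table).
#' @export
build_concat_index <- function(genomes, k = 21) {
  if (k %% 2 != 1 || k < 11 || k > 31) stop("k must be odd and in [11, 31]")
  if (!is.null(genomes$sequences_A)) {
    genomes <- list(A = genomes$sequences_A, B = genomes$sequences_B)
  }
  gnames <- names(genomes)
  occ <- list()
  for (g in gnames) {
    for (chrom in names(genomes[[g]])) {
      s <- genomes[[g]][[chrom]]
      if (nchar(s) < k) stop("sequence ", g, "/", chrom, " shorter than k")
      dt <- seq_kmers(s, k)
      dt[, `:=`(genome = g, chrom = chrom)]
      occ[[length(occ) + 1L]] <- dt
    }
  }
  occ <- data.table::rbindlist(occ)
  # drop ambiguous-base k-mers (masked regions)
  occ <- occ[!grepl("N", kmer, fixed = TRUE)]
  data.table::setkey(occ, kmer)

  pres <- unique(occ[, .(kmer, genome)])
  cls <- pres[, .(n_genomes = .N, genome1 = genome[1]), by = kmer]
  cls[, class := ifelse(n_genomes == 1L, genome1, "shared")]
  cls <- cls[, .(kmer, class)]
  data.table::setkey(cls, kmer)

  structure(list(k = as.integer(k), genome_names = gnames,
                 occ = occ, class = cls),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k=", x$k, ", genomes: ",
      paste(x$genome_names, collapse = ", "),
      ", distinct k-mers: ", nrow(x$class), "\n", sep = "")
  invisible(x)
}

#' Number of distinct indexed k-mers
#'
#' @param index A `kmer_index`.
#' @return Integer count of distinct canonical k-mers.
#' @export
n_distinct_kmers <- function(index) nrow(index$class)
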