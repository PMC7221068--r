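BASES <- c("A", "C", "G", "T")

# mutate a character vector of bases at per-site rate r, substitution to one of
# the three other bases uniformly
mutate_lineage <- function(bases, rate) {
  n <- length(bases)
  hit <- which(runif(n) < rate)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    idx <- match(bases[hit], BASES)
    bases[hit] <- BASES[((idx - 1L + shift) %% 4L) + 1L]
  }
  bases
}

# per-lineage substitution rate r such that two lineages mutated independently
# from a common ancestor show an expected pairwise mismatch fraction d:
#   P(mismatch) = 2 r (1 - r) + (2/3) r^2  =>  (4/3) r^2 - 2 r + d = 0
lineage_rate <- function(divergence) {
  if (divergence == 0) return(0)
  (2 - sqrt(4 - (16 / 3) * divergence)) / (8 / 3)
}

#' Generate a pair of diverged genomes with annotations and an ortholog map
#'
#' An ancestral random genome is mutated independently along two lineages (A
#' and B) so that the expected pairwise per-site mismatch fraction between
#' homologous positions equals `divergence`. Substitutions only, no indels:
#' homologous chromosomes have equal length and homology is positional, which
#' keeps read-level truth-tracking exact. Genes are placed without overlap at
#' identical positions in both genomes, on random strands, and the ortholog map
#' is the identity on gene indices.
#'
#' The default divergence of 0.2 matches the coding-region nucleotide
#' divergence between the two yeast species whose hybrid motivates this
#' package.
#'
#' @param n_chrom Number of chromosomes (default 2).
#' @param chrom_len Chromosome length in bp (default 100000).
#' @param n_genes Total number of genes across chromosomes (default 300).
#' @param divergence Expected per-site mismatch fraction, in `[0, 0.5]`.
#' @param gene_len_range Gene lengths are drawn uniformly from this bp range.
#' @param seed Integer seed; identical inputs give byte-identical outputs.
#' @return A list with components:
#'   * `genomes`: list with `sequences_A`, `sequences_B` (named character
#'     vectors per chromosome), `divergence`, `chrom_lengths`;
#'   * `orthologs`: `data.frame(gene_A, gene_B, len_A, len_B, chrom, start,
#'     end, strand)` (1-based inclusive coordinates, as in GTF);
#'   * `annotation_A`, `annotation_B`: per-genome `data.frame(gene_id, chrom,
#'     start, end, strand)`.
#' @export
generate_genome_pair <- function(n_chrom = 2, chrom_len = 100000,
                                 n_genes = 300, divergence = 0.2,
                                 gene_len_range = c(200, 600),
                                 seed = 1) {
  check_fraction(divergence, "divergence", 0, 0.5)
  if (n_genes < 1) stop("n_genes must be >= 1")
  set.seed(seed)

  rate <- lineage_rate(divergence)
  seq_A <- seq_B <- character(n_chrom)
  names(seq_A) <- names(seq_B) <- paste0("chr", seq_len(n_chrom))
  for (i in seq_len(n_chrom)) {
    anc <- sample(BASES, chrom_len, replace = TRUE)
    seq_A[i] <- paste(mutate_lineage(anc, rate), collapse = "")
    seq_B[i] <- paste(mutate_lineage(anc, rate), collapse = "")
  }

  # distribute genes over chromosomes as evenly as possible
  per_chrom <- rep(n_genes %/% n_chrom, n_chrom)
  extra <- n_genes %% n_chrom
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L

  ann <- vector("list", n_chrom)
  for (i in seq_len(n_chrom)) {
    m <- per_chrom[i]
    if (m == 0) next
    lens <- as.integer(round(runif(m, gene_len_range[1], gene_len_range[2])))
    slack <- chrom_len - sum(lens)
    if (slack < 0) {
      stop("genes cannot be placed without overlap at the requested density")
    }
    # random gap partition: m+1 gaps summing to the slack
    cuts <- sort(sample.int(slack + 1L, m, replace = TRUE) - 1L)
    gaps <- diff(c(0L, cuts, slack))
    starts <- as.integer(cumsum(gaps[seq_len(m)] + c(0L, lens[-m])) + 1L)
    ann[[i]] <- data.frame(
      chrom = names(seq_A)[i],
      start = starts,                       # 1-based inclusive
      end = starts + lens - 1L,
      strand = sample(c("+", "-"), m, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  ann <- do.call(rbind, ann)
  ann$gene_id <- sprintf("g%04d", seq_len(nrow(ann)))
  ann <- ann[, c("gene_id", "chrom", "start", "end", "strand")]

  annotation_A <- transform(ann, gene_id = paste0("A_", gene_id))
  annotation_B <- transform(ann, gene_id = paste0("B_", gene_id))
  orthologs <- data.frame(
    gene_A = annotation_A$gene_id,
    gene_B = annotation_B$gene_id,
    len_A = ann$end - ann$start + 1L,
    len_B = ann$end - ann$start + 1L,
    chrom = ann$chrom,
    start = ann$start,
    end = ann$end,
    strand = ann$strand,
    stringsAsFactors = FALSE
  )

  list(
    genomes = list(
      sequences_A = seq_A,
      sequences_B = seq_B,
      divergence = divergence,
      chrom_lengths = setNames(rep(chrom_len, n_chrom), names(seq_A))
    ),
    orthologs = orthologs,
    annotation_A = annotation_A,
    annotation_B = annotation_B
  )
}

#' Observed per-site mismatch fraction between two equal-length genomes
#'
#' @param genomes A `genomes` list as returned by [generate_genome_pair()].
#' @return Fraction of homologous positions that differ.
#' @export
observed_divergence <- function(genomes) {
  a <- strsplit(paste(genomes$sequences_A, collapse = ""), "")[[1]]
  b <- strsplit(paste(genomes$sequences_B, collapse = ""), "")[[1]]
  if (length(a) != length(b)) stop("genomes differ in length")
  mean(a != b)
}

#' Write genome FASTA files
#'
#' @param genomes `genomes` list from [generate_genome_pair()].
#' @param path_A,path_B Output FASTA paths for the two genomes.
#' @return Invisibly, the two paths.
#' @export
write_genome_fasta <- function(genomes, path_A, path_B) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genomes$sequences_A), path_A)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genomes$sequences_B), path_B)
  invisible(c(path_A, path_B))
}

#' Write a gene annotation in GTF format (1-based inclusive)
#'
#' @param annotation Annotation `data.frame` from [generate_genome_pair()].
#' @param path Output GTF path.
#' @param source Source field for the GTF records.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path, source = "hybridshock") {
  lines <- sprintf(
    '%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    annotation$chrom, source, annotation$start, annotation$end,
    annotation$strand, annotation$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation from GTF
#'
#' Only `gene` records are retained; coordinates stay 1-based inclusive.
#'
#' @param path GTF file.
#' @return `data.frame(gene_id, chrom, start, end, strand)`.
#' @export
read_annotation_gtf <- function(path) {
  df <- read.table(path, sep = "\t", quote = "", comment.char = "#",
                   stringsAsFactors = FALSE)
  df <- df[df[[3]] == "gene", , drop = FALSE]
  gene_id <- sub('.*gene_id "([^"]+)".*', "\\1", df[[9]])
  data.frame(gene_id = gene_id, chrom = df[[1]], start = df[[4]],
             end = df[[5]], strand = df[[7]], stringsAsFactors = FALSE)
}

#' Write / read a one-to-one ortholog map as TSV
#'
#' @param orthologs Ortholog `data.frame` from [generate_genome_pair()].
#' @param path TSV path.
#' @return `path` (write) or the `data.frame` (read).
#' @export
write_ortholog_map <- function(orthologs, path) {
  write.table(orthologs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_map
#' @export
read_ortholog_map <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
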