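#' Simulate sequencing reads with truth-tracking names
#'
#' Reads are sampled uniformly over chromosome positions (weighted by the
#' number of valid start positions) and strands, with independent per-base
#' substitution errors at `error_rate`. Read names encode the true origin as
#' `id|genome|chrom|start|strand` (1-based start on the forward strand of the
#' source chromosome), so downstream assignment can be scored against the
#' truth.
#'
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences for one genome.
#' @param n_reads Number of reads.
#' @param read_len Read length in bp; must not exceed the shortest chromosome.
#' @param error_rate Per-base substitution probability.
#' @param genome_label Genome label recorded in read names (e.g. `"A"`).
#' @param seed Integer seed.
#' @return A named character vector of read sequences (names carry the truth).
#' @export
simulate_reads <- function(genome, n_reads, read_len, error_rate = 0,
                           genome_label = "A", seed = 1) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  check_fraction(error_rate, "error_rate")
  lens <- nchar(genome)
  if (read_len > min(lens)) {
    stop("read_len exceeds the shortest chromosome")
  }
  set.seed(seed)

  n_pos <- lens - read_len + 1L
  chrom_idx <- sample.int(length(genome), n_reads, replace = TRUE,
                          prob = n_pos)
  starts <- floor(runif(n_reads) * n_pos[chrom_idx]) + 1L
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)

  reads <- substring(genome[chrom_idx], starts, starts + read_len - 1L)
  rev <- strands == "-"
  if (any(rev)) {
    reads[rev] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(reads[rev])))
  }

  if (error_rate > 0) {
    total <- n_reads * read_len
    hit <- which(runif(total) < error_rate)
    if (length(hit)) {
      read_of <- ((hit - 1L) %/% read_len) + 1L
      pos_of <- ((hit - 1L) %% read_len) + 1L
      cur <- substring(reads[read_of], pos_of, pos_of)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      new <- BASES[((match(cur, BASES) - 1L + shift) %% 4L) + 1L]
      for (j in seq_along(hit)) {
        substr(reads[read_of[j]], pos_of[j], pos_of[j]) <- new[j]
      }
    }
  }

  reads <- unname(reads)
  names(reads) <- sprintf("rd%06d|%s|%s|%d|%s", seq_len(n_reads),
                          genome_label, names(genome)[chrom_idx], starts,
                          strands)
  reads
}

#' Parse truth fields from simulated read names
#'
#' @param read_names Character vector of names produced by [simulate_reads()].
#' @return `data.frame(read, genome, chrom, start, strand)`; rows are `NA`
#'   where a name does not carry truth fields.
#' @export
parse_read_truth <- function(read_names) {
  parts <- strsplit(read_names, "|", fixed = TRUE)
  ok <- lengths(parts) == 5L
  get <- function(i) vapply(parts, function(p)
    if (length(p) == 5L) p[i] else NA_character_, character(1))
  data.frame(
    read = read_names,
    genome = get(2), chrom = get(3),
    start = suppressWarnings(as.integer(get(4))),
    strand = get(5),
    stringsAsFactors = FALSE
  )[, ]
}

#' Write / read reads in FASTQ
#'
#' Quality strings are constant (`"I"`, Phred 40): quality modeling is out of
#' scope for these fixtures.
#'
#' @param reads Named character vector of read sequences.
#' @param path FASTQ path.
#' @return `path` (write) or a named character vector of reads (read).
#' @export
write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(unname(reads))
  names(dss) <- names(reads)
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(dss), names(dss))
}
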