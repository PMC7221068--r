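Package: hybridshock
Title: Quantifying Transcriptional and Chromatin Shock After Interspecies Hybridization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the magnitude of the transcriptional and chromatin
    "shock" that follows interspecies hybridization, using yeast-style
    diploid hybrids as the model. Provides allele-aware read assignment to
    concatenated parental references with cross-mapping estimation,
    negative-binomial differential expression with length-aware
    allele-specific normalization, a four-way contrast design (parents,
    genetic backgrounds, homeologs, temperature), classification of
    allele-specific expression into inherited, acquired, attenuated and
    conserved categories with modulon-scenario quantification, and
    ATAC-style chromatin occupancy and differential-accessibility analysis
    integrated with expression. A synthetic-data module generates diverged
    genome pairs, annotated count matrices with designed effect structure,
    reads and replicate peak sets so the whole pipeline is testable against
    known ground truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rlang,
    rtracklayer,
    stats,
    utils
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
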