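test_that("region masking replaces exactly the half-open interval with N", {
  set.seed(91)
  genome <- c(chrM = paste(sample(c("A", "C", "G", "T"), 100, TRUE),
                           collapse = ""))
  # empty region set: unchanged
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  expect_identical(mask_regions(genome, empty), genome)

  masked <- mask_regions(genome, data.frame(chrom = "chrM", start = 10,
                                            end = 20))
  expect_equal(sum(strsplit(masked[["chrM"]], "")[[1]] == "N"), 10)
  expect_identical(substr(masked[["chrM"]], 1, 10),
                   substr(genome[["chrM"]], 1, 10))
  expect_identical(substr(masked[["chrM"]], 21, 100),
                   substr(genome[["chrM"]], 21, 100))

  expect_error(mask_regions(genome, data.frame(chrom = "chrM", start = 50,
                                               end = 200)), "bounds")

  # the two rDNA-style regions on a synthetic 500 kb chromosome XII
  set.seed(92)
  chr12 <- c(chrXII = paste(sample(c("A", "C", "G", "T"), 500000, TRUE),
                            collapse = ""))
  rdna <- data.frame(chrom = "chrXII", start = c(450915, 489349),
                     end = c(469179, 490611))
  masked12 <- mask_regions(chr12, rdna)
  n_count <- sum(strsplit(masked12[["chrXII"]], "")[[1]] == "N")
  expect_equal(n_count, 18264 + 1262)
})

test_that("replicate consensus merges unions supported by min_reps", {
  p1 <- peak_set("chr1", c(100, 500), c(200, 600), score = c(10, 20))
  p2 <- peak_set("chr1", c(150, 800), c(250, 900), score = c(30, 40))
  p3 <- peak_set("chr1", 100, 200, score = 50)

  # identical replicates pass through
  cons_same <- replicate_consensus(list(p1, p1), min_reps = 2)
  expect_equal(cons_same$start, p1$start)
  expect_equal(cons_same$end, p1$end)
  expect_equal(cons_same$score, p1$score)

  # union semantics: [100,200) + [150,250) -> [100,250), mean score
  cons <- replicate_consensus(list(p1, p2), min_reps = 2)
  expect_equal(cons$start, 100)
  expect_equal(cons$end, 250)
  expect_equal(cons$score, 20)

  # a peak in 1 of 3 replicates is dropped at min_reps = 2
  cons3 <- replicate_consensus(list(p1, p2, p3), min_reps = 2)
  expect_false(any(cons3$start >= 450))   # the 500/800 peaks are singletons

  expect_error(replicate_consensus(list(p1), min_reps = 2), "min_reps")
})

test_that("peak-set partition is exhaustive and symmetric", {
  a <- peak_set("chr1", c(0, 1000, 2000), c(300, 1300, 2300),
                score = c(5, 6, 7))
  b <- peak_set("chr1", c(100, 5000), c(400, 5300), score = c(8, 9))
  part <- partition_peaksets(a, b)
  expect_equal(part$counts[["consensus_from_parent"]] +
                 part$counts[["parent_specific"]], nrow(a))
  expect_equal(part$counts[["consensus_from_hybrid"]] +
                 part$counts[["hybrid_specific"]], nrow(b))
  expect_equal(part$counts[["consensus_from_parent"]], 1)
  expect_equal(part$counts[["hybrid_specific"]], 1)

  # disjoint and identical extremes
  disj <- partition_peaksets(
    peak_set("chr1", 0, 100, 1), peak_set("chr1", 500, 600, 1))
  expect_equal(disj$counts[["consensus_from_parent"]], 0)
  expect_equal(disj$counts[["parent_specific"]], 1)
  same <- partition_peaksets(a, a)
  expect_equal(same$counts[["parent_specific"]], 0)
  expect_equal(same$counts[["consensus_from_parent"]], nrow(a))

  expect_error(partition_peaksets(
    peak_set("chr1", 0, 10, 1), peak_set("chr9", 0, 10, 1)),
    "no chromosome")
})

test_that("interval overlap matches a brute-force per-base oracle", {
  set.seed(93)
  for (rep in 1:5) {
    s1 <- sort(sample(0:500, 8)); e1 <- s1 + sample(10:80, 8, TRUE)
    s2 <- sort(sample(0:500, 8)); e2 <- s2 + sample(10:80, 8, TRUE)
    a <- peak_set("chr1", s1, e1, score = 1)
    b <- peak_set("chr1", s2, e2, score = 1)
    part <- partition_peaksets(a, b)
    # brute force: does peak i of a share any base with any peak of b?
    covered_b <- unique(unlist(mapply(seq, b$start, b$end - 1L,
                                      SIMPLIFY = FALSE)))
    hit_a <- vapply(seq_len(nrow(a)), function(i)
      any(seq(a$start[i], a$end[i] - 1L) %in% covered_b), logical(1))
    expect_equal(part$counts[["consensus_from_parent"]], sum(hit_a))
    # symmetry: A overlaps B iff B overlaps A, in aggregate on these sets
    covered_a <- unique(unlist(mapply(seq, a$start, a$end - 1L,
                                      SIMPLIFY = FALSE)))
    hit_b <- vapply(seq_len(nrow(b)), function(i)
      any(seq(b$start[i], b$end[i] - 1L) %in% covered_a), logical(1))
    expect_equal(part$counts[["consensus_from_hybrid"]], sum(hit_b))
    expect_equal(any(hit_a), any(hit_b))
  }
})

test_that("score comparison agrees with enumeration and detects shifts", {
  # identical distributions: large p
  set.seed(94)
  x <- rnorm(100, 500, 50)
  sc0 <- score_comparison(list(a = x, b = sample(x)))
  expect_gt(sc0$p_value, 0.5)

  # tiny groups: exact permutation oracle gives 0.1; the normal
  # approximation must land close to it
  p_exact <- oracle_ranksum_p(c(1, 2, 3), c(10, 20, 30))
  expect_equal(p_exact, 0.1)
  sc1 <- score_comparison(list(lo = c(1, 2, 3), hi = c(10, 20, 30)))
  expect_lt(abs(sc1$p_value - p_exact), 0.05)

  # specific peaks scoring lower than consensus: strong signal at n >= 100
  set.seed(95)
  sc2 <- score_comparison(list(specific = rnorm(120, 350, 120),
                               consensus = rnorm(600, 600, 120)))
  expect_lt(sc2$p_value, 0.01)

  expect_error(score_comparison(list(a = 1:3, b = numeric(0))), "non-empty")
})

test_that("promoters are strand-aware, truncated and non-genic", {
  # + strand gene with an upstream neighbor ending at 4500 (0-based)
  ann <- data.frame(gene_id = c("up", "g"), chrom = "chr1",
                    start = c(4001, 5001), end = c(4500, 6000),
                    strand = c("+", "+"))
  pm <- define_promoters(ann, c(chr1 = 20000))
  g <- pm[pm$gene_id == "g", ]
  expect_equal(c(g$start, g$end), c(4500, 5000))
  expect_equal(g$reason, "neighbor_gene")

  # + strand gene near the chromosome start
  ann2 <- data.frame(gene_id = "g2", chrom = "chr1", start = 301, end = 900,
                     strand = "+")
  pm2 <- define_promoters(ann2, c(chr1 = 10000))
  expect_equal(c(pm2$start, pm2$end), c(0, 300))
  expect_equal(pm2$reason, "chromosome_border")

  # isolated - strand gene gets the full 1 kb downstream-in-coordinates
  ann3 <- data.frame(gene_id = "g3", chrom = "chr1", start = 2001, end = 3000,
                     strand = "-")
  pm3 <- define_promoters(ann3, c(chr1 = 10000))
  expect_equal(c(pm3$start, pm3$end), c(3000, 4000))
  expect_equal(pm3$reason, "full_1kb")

  # invariants on a generated annotation: lengths in [0, 1000], and no
  # promoter overlaps any gene body
  gp <- small_pair()
  pm4 <- define_promoters(gp$annotation_A, gp$genomes$chrom_lengths)
  expect_true(all(pm4$length >= 0 & pm4$length <= 1000))
  gene_gr <- GenomicRanges::GRanges(
    gp$annotation_A$chrom,
    IRanges::IRanges(gp$annotation_A$start, gp$annotation_A$end))
  ok <- pm4$length > 0
  prom_gr <- GenomicRanges::GRanges(
    pm4$chrom[ok], IRanges::IRanges(pm4$start[ok] + 1L, pm4$end[ok]))
  expect_equal(sum(GenomicRanges::countOverlaps(prom_gr, gene_gr)), 0)
})

test_that("promoter coverage sums match the per-base oracle", {
  prom <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                     start = 100, end = 600, length = 500,
                     reason = "full_1kb")
  # uniform coverage 1 across the promoter
  cov1 <- data.frame(chrom = "chr1", start = 0, end = 1000, value = 1)
  expect_equal(unname(promoter_counts(cov1, prom)), 500)
  # zero coverage
  cov0 <- data.frame(chrom = "chr1", start = 0, end = 1000, value = 0)
  expect_equal(unname(promoter_counts(cov0, prom)), 0)
  # two half-overlapping blocks, cross-checked base by base
  cov2 <- data.frame(chrom = "chr1", start = c(50, 300), end = c(400, 800),
                     value = c(2, 3.5))
  expect_equal(unname(promoter_counts(cov2, prom)),
               oracle_coverage_sum(cov2, "chr1", 100, 600))

  expect_error(promoter_counts(
    data.frame(chrom = "chrX", start = 0, end = 10, value = 1), prom),
    "absent")
})

test_that("differential accessibility controls for promoter length", {
  # equal counts, equal lengths: nothing called
  cts <- matrix(rep(c(500L, 510L, 495L, 505L, 498L, 502L), 50), 50,
                byrow = TRUE, dimnames = list(paste0("r", 1:50), NULL))
  lens <- matrix(800, 50, 6)
  grp <- rep(c("A", "B"), each = 3)
  da0 <- differential_accessibility(cts, lens, grp)
  expect_equal(nrow(da0$more_open) + nrow(da0$less_open), 0)

  # designed 4x accessibility on 20 of 200 regions: >= 16 recovered
  rec <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 200
    lens <- matrix(runif(n, 300, 1000), n, 6)
    eff <- c(rep(2, 20), rep(0, n - 20))
    mu <- cbind(matrix(lens[, 1] * 2^(-eff / 2), n, 3),
                matrix(lens[, 1] * 2^(eff / 2), n, 3))
    cts <- matrix(rnbinom(n * 6, mu = as.vector(mu), size = 1 / 0.02), n,
                  dimnames = list(sprintf("r%03d", 1:n), NULL))
    da <- differential_accessibility(cts, lens, grp)
    sum(da$more_open$gene %in% sprintf("r%03d", 1:20))
  }, numeric(1))
  expect_true(all(rec >= 16))

  # 2x longer B-side promoters (for a third of the regions) with equal true
  # accessibility: silent after length control, ~l2fc -1 bias without it
  set.seed(96)
  n <- 150
  ratio <- rep(c(2, 1, 1), length.out = n)
  lensb <- cbind(matrix(1000, n, 3), matrix(1000 * ratio, n, 3))
  mu <- lensb  # reads proportional to length only
  ctsb <- matrix(rnbinom(n * 6, mu = as.vector(mu), size = 1 / 0.01), n,
                 dimnames = list(sprintf("r%03d", 1:n), NULL))
  dab <- differential_accessibility(ctsb, lensb, grp, numerator = "A",
                                    denominator = "B")
  expect_equal(nrow(dab$more_open) + nrow(dab$less_open), 0)
  alb <- estimate_dispersion(ctsb, rep(1, 6), grp)
  biased <- nb_wald(ctsb, grp, rep(1, 6), alb, "A", "B")
  expect_lt(abs(median(biased$l2fc[ratio == 2]) + 1), 0.15)
  expect_lt(abs(median(biased$l2fc[ratio == 1])), 0.15)
})

test_that("peaks link to genes through promoter overlap within 1 kb", {
  ann <- data.frame(
    gene_id = c("left", "right"), chrom = "chr1",
    start = c(1001, 3001), end = c(2000, 4000),
    strand = c("-", "+"))  # divergent pair: promoters share [2000, 3000)
  pm <- define_promoters(ann, c(chr1 = 10000))
  peaks <- peak_set("chr1", c(2100, 8000), c(2400, 8200), score = c(5, 5),
                    name = c("pk_mid", "pk_far"))
  links <- assign_peaks_to_genes(peaks, ann, pm)
  mid <- links[links$peak == "pk_mid" & !is.na(links$gene_id), ]
  expect_setequal(mid$gene_id, c("left", "right"))   # both divergent genes
  far <- links[links$peak == "pk_far", ]
  expect_true(all(is.na(far$gene_id)))               # > 1 kb from any gene

  # a peak inside one promoter links to exactly that gene
  solo <- assign_peaks_to_genes(
    peak_set("chr1", 2900, 2990, 1, name = "pk_near_right"), ann, pm)
  near <- solo[!is.na(solo$gene_id), ]
  expect_true("right" %in% near$gene_id)
})

test_that("expression integration reports concordance faithfully", {
  empty <- integrate_expression(
    data.frame(gene_id = character(0), access_direction = integer(0)),
    data.frame(gene = "g1", direction = 1L))
  expect_equal(sum(empty$concordance), 0)

  # accessibility and expression placed on the same 10 genes: 10/10
  links <- data.frame(gene_id = paste0("g", 1:10),
                      access_direction = rep(c(1L, -1L), 5))
  de <- data.frame(gene = paste0("g", 1:10),
                   direction = rep(c(1L, -1L), 5))
  ic <- integrate_expression(links, de)
  expect_equal(unname(ic$concordance["same_direction"]), 10)

  # independent placement: same-direction count matches the hypergeometric
  # expectation within 3 sigma (averaged over draws)
  set.seed(97)
  n_genes <- 400; n_de <- 60; n_links <- 50
  same <- vapply(1:20, function(i) {
    de_i <- data.frame(gene = sample(paste0("g", 1:n_genes), n_de),
                       direction = sample(c(1L, -1L), n_de, TRUE))
    li <- data.frame(gene_id = sample(paste0("g", 1:n_genes), n_links),
                     access_direction = sample(c(1L, -1L), n_links, TRUE))
    integrate_expression(li, de_i)$concordance[["same_direction"]]
  }, numeric(1))
  expected <- n_links * (n_de / n_genes) / 2   # direction agrees half the time
  se3 <- 3 * sd(same) / sqrt(length(same))
  expect_lt(abs(mean(same) - expected), max(se3, 1.5))
})

test_that("narrowPeak and bedGraph files round-trip", {
  pk <- peak_set("chr2", c(10, 500), c(200, 900), score = c(123.4, 77.1),
                 name = c("a", "b"), provenance = "rep1")
  np <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(pk, np)
  back <- read_narrowpeak(np, provenance = "rep1")
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$score, pk$score, tolerance = 1e-8)

  cov <- data.frame(chrom = "chr2", start = c(0L, 100L), end = c(100L, 250L),
                    value = c(1.5, 3))
  bg <- tempfile(fileext = ".bedGraph")
  write_bedgraph(cov, bg)
  expect_equal(read_bedgraph(bg), cov)
})
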