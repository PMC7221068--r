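test_that("median-of-ratios size factors match hand computation and scaling", {
  expect_equal(size_factors(matrix(c(10, 30, 20, 60), nrow = 2)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)

  m <- matrix(rep(c(40, 70, 15), 4), nrow = 4, byrow = TRUE)
  expect_equal(unname(size_factors(cbind(m[, 1], m[, 1], m[, 1]))),
               rep(1, 3))
})

test_that("doubling one sample's counts doubles its factor", {
  set.seed(71)
  cts <- matrix(rnbinom(200 * 4, mu = 200, size = 10), 200)
  sf1 <- size_factors(cts)
  cts2 <- cts
  cts2[, 2] <- cts[, 2] * 2L
  sf2 <- size_factors(cts2)
  ratio <- sf2 / sf1
  # all relative factors shift by the common rescale c; sample 2 gains 2c
  expect_equal(unname(ratio[2] / ratio[1]), 2, tolerance = 1e-10)
  expect_equal(unname(ratio[3] / ratio[1]), 1, tolerance = 1e-10)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "no gene")
})

test_that("size factors agree with the reference implementation", {
  set.seed(72)
  cts <- matrix(rnbinom(300 * 6, mu = 500, size = 5), 300)
  sf <- size_factors(cts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(cts)
  # identical up to the geometric-mean-1 rescale
  expect_equal(unname(sf / ref), rep(unname((sf / ref))[1], 6),
               tolerance = 1e-10)
})

test_that("allele length factors implement lengths over row geometric means", {
  expect_equal(unname(allele_length_factors(
    matrix(c(1000, 4000), nrow = 1))[1, ]), c(0.5, 2))
  eq <- matrix(1200, nrow = 5, ncol = 4)
  expect_true(all(allele_length_factors(eq) == 1))

  # per-gene product over 2 samples is 1; geometric mean is 1 for any width
  set.seed(73)
  two <- matrix(runif(40, 200, 5000), ncol = 2)
  expect_equal(apply(allele_length_factors(two), 1, prod), rep(1, 20),
               tolerance = 1e-12)
  wide <- matrix(runif(60, 200, 5000), ncol = 6)
  gm <- exp(rowMeans(log(allele_length_factors(wide))))
  expect_true(all(abs(gm - 1) < 1e-9))

  expect_error(allele_length_factors(matrix(c(0, 100), 1)), "positive")
})

test_that("length-and-library factors remove ortholog length bias", {
  # equal lengths: reduces to plain library-size normalization
  set.seed(74)
  cts <- matrix(rnbinom(100 * 6, mu = 400, size = 20), 100)
  lens <- matrix(1500, 100, 6)
  nf <- length_and_library_factors(lens, cts)
  sf <- size_factors(cts)
  expect_equal(nf, matrix(sf, 100, 6, byrow = TRUE), tolerance = 1e-12)

  # 2x longer orthologs in species B, equal true expression:
  # corrected l2fc ~ 0, uncorrected l2fc ~ -1 (length bias)
  grp <- rep(c("A", "B"), each = 3)
  reps <- vapply(1:6, function(s) {
    set.seed(200 + s)
    g <- 150
    lens <- cbind(matrix(1000, g, 3), matrix(2000, g, 3))
    mu <- cbind(matrix(1000, g, 3), matrix(2000, g, 3))  # reads ~ length
    cts <- matrix(rnbinom(g * 6, mu = as.vector(mu), size = 1 / 0.01), g,
                  dimnames = list(sprintf("g%03d", 1:g), NULL))
    nf <- length_and_library_factors(lens, cts)
    al <- estimate_dispersion(cts, nf, grp)
    corrected <- median(nb_wald(cts, grp, nf, al, "A", "B")$l2fc)
    sf_only <- matrix(rep(1, 6), g, 6, byrow = TRUE)
    al2 <- estimate_dispersion(cts, sf_only, grp)
    plain <- median(nb_wald(cts, grp, sf_only, al2, "A", "B")$l2fc)
    c(corrected, plain)
  }, numeric(2))
  expect_lt(max(abs(reps[1, ])), 0.15)
  expect_true(all(abs(reps[2, ] + 1) < 0.15))
})

test_that("dispersion estimation is consistent at both ends", {
  grp <- rep(c("a", "b"), each = 3)
  # Poisson data: near-zero dispersion
  set.seed(75)
  cts <- matrix(rpois(300 * 6, 1000), 300,
                dimnames = list(sprintf("g%03d", 1:300), NULL))
  al <- estimate_dispersion(cts, rep(1, 6), grp)
  expect_lte(median(al), 0.01)

  # true alpha = 0.1: median estimate within [0.05, 0.2] across seeds
  med <- vapply(1:10, function(s) {
    set.seed(s)
    cts <- matrix(rnbinom(300 * 6, mu = 1000, size = 10), 300,
                  dimnames = list(sprintf("g%03d", 1:300), NULL))
    median(estimate_dispersion(cts, rep(1, 6), grp))
  }, numeric(1))
  expect_true(all(med >= 0.05 & med <= 0.2))

  # constant counts within groups: floor
  cts_const <- matrix(rep(c(100L, 200L), each = 3), 4, 6, byrow = TRUE,
                      dimnames = list(paste0("g", 1:4), NULL))
  al_const <- estimate_dispersion(cts_const, rep(1, 6), grp)
  expect_true(all(al_const == 1e-8))

  expect_error(estimate_dispersion(cts_const, rep(1, 6),
                                   c("a", "a", "a", "a", "a", "b")),
               "at least 2 replicates")
})

test_that("NB Wald recovers designed effects with honest uncertainty", {
  grp <- rep(c("a", "b"), each = 3)
  # identical groups: l2fc 0, p 1
  cts <- matrix(rep(c(100L, 300L), 6), 2, 6,
                dimnames = list(c("g1", "g2"), NULL))
  al <- estimate_dispersion(cts, rep(1, 6), grp)
  res0 <- nb_wald(cts, grp, rep(1, 6), al, "b", "a")
  expect_equal(res0$l2fc, c(0, 0), tolerance = 1e-8)
  expect_equal(res0$p, c(1, 1), tolerance = 1e-6)

  # all-zero genes: p = 1, l2fc = 0, flagged
  ctsz <- rbind(g0 = rep(0L, 6), gA = c(500L, 520L, 480L, 110L, 95L, 101L))
  alz <- estimate_dispersion(ctsz, rep(1, 6), grp)
  resz <- nb_wald(ctsz, grp, rep(1, 6), alz, "a", "b")
  expect_equal(resz$l2fc[1], 0)
  expect_equal(resz$p[1], 1)
  expect_equal(resz$flag[1], "all_zero")

  # mu 1000 vs 4000 at alpha 0.01, 3v3: l2fc in [1.7, 2.3], p < 1e-4 for
  # at least 95% of simulated genes (40 genes x 5 seeds stands in for the
  # 200-seed single-gene version)
  hits <- unlist(lapply(1:5, function(s) {
    set.seed(s)
    g <- 40
    cts <- cbind(matrix(rnbinom(g * 3, mu = 4000, size = 100), g),
                 matrix(rnbinom(g * 3, mu = 1000, size = 100), g))
    rownames(cts) <- paste0("g", 1:g)
    al <- estimate_dispersion(cts, rep(1, 6), grp)
    res <- nb_wald(cts, grp, rep(1, 6), al, "a", "b")
    res$l2fc >= 1.7 & res$l2fc <= 2.3 & res$p < 1e-4
  }))
  expect_gte(mean(hits), 0.95)
})

test_that("Wald type-I error is calibrated at nominal 0.05", {
  grp <- rep(c("a", "b"), each = 3)
  rate <- mean(vapply(1:8, function(s) {
    set.seed(s)
    g <- 300
    mu <- exp(runif(g, log(100), log(2000)))
    cts <- matrix(rnbinom(g * 6, mu = rep(mu, 6), size = 20), g,
                  dimnames = list(sprintf("g%03d", 1:g), NULL))
    sf <- size_factors(cts)
    al <- estimate_dispersion(cts, sf, grp)
    res <- nb_wald(cts, grp, sf, al, "b", "a")
    mean(res$p < 0.05, na.rm = TRUE)
  }, numeric(1)))
  expect_gte(rate, 0.025)
  expect_lte(rate, 0.085)
})

test_that("contrasts are antisymmetric and normalization-equivariant", {
  set.seed(76)
  g <- 80
  grp <- rep(c("a", "b"), each = 3)
  cts <- matrix(rnbinom(g * 6, mu = 600, size = 15), g,
                dimnames = list(sprintf("g%02d", 1:g), NULL))
  sf <- size_factors(cts)
  al <- estimate_dispersion(cts, sf, grp)
  fwd <- nb_wald(cts, grp, sf, al, "a", "b")
  rev <- nb_wald(cts, grp, sf, al, "b", "a")
  expect_equal(fwd$l2fc, -rev$l2fc, tolerance = 1e-6)
  expect_equal(fwd$p, rev$p, tolerance = 1e-8)

  # multiplying one sample's counts by c and its factors by c changes no
  # l2fc (exact under Poisson weights; the NB weight ratio reintroduces a
  # tiny dependence, so the invariant is asserted at alpha = 0)
  nf <- matrix(sf, g, 6, byrow = TRUE, dimnames = dimnames(cts))
  cts2 <- cts; cts2[, 1] <- cts[, 1] * 3L
  nf2 <- nf; nf2[, 1] <- nf[, 1] * 3
  a0 <- rep(0, g)
  r1 <- nb_wald(cts, grp, nf, a0, "a", "b")
  r2 <- nb_wald(cts2, grp, nf2, a0, "a", "b")
  expect_equal(r1$l2fc, r2$l2fc, tolerance = 1e-6)
})

test_that("effect estimates agree with the reference NB engine", {
  sim <- sim_nb_matrix(120, mu = 800, alpha = 0.05, l2fc = 2,
                       n_affected = 30, seed = 77)
  sf <- size_factors(sim$counts)
  al <- estimate_dispersion(sim$counts, sf, sim$group)
  res <- nb_wald(sim$counts, sim$group, sf, al, "A", "B")

  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    sim$counts, data.frame(g = factor(sim$group, levels = c("B", "A"))),
    ~g))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- DESeq2::results(dds)
  expect_gt(cor(res$l2fc, ref$log2FoldChange), 0.98)
  expect_lt(median(abs(res$l2fc - ref$log2FoldChange)), 0.1)
})

test_that("BH adjustment matches the hand example and the reference", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(78)
  for (i in 1:20) {
    p <- runif(sample(1:10, 1))
    if (i %% 3 == 0) p[sample(length(p), 1)] <- NA
    expect_identical(adjust_bh(p), stats::p.adjust(p, method = "BH"))
  }
})

test_that("DE calling uses strict threshold inequalities", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    base_mean = c(50, 50, 50, 5),
                    l2fc = c(1.6, 1.5, -2.0, 3.0),
                    padj = c(0.005, 0.001, 0.5, 0.001))
  de <- call_de(res, l2fc_min = 1.5, padj_max = 0.01)
  expect_identical(de$gene, c("a", "d"))
  expect_identical(de$direction, c(1L, 1L))
  # exactly at the threshold is NOT called
  expect_false("b" %in% de$gene)
  expect_false("c" %in% de$gene)
  # optional expression floor
  de2 <- call_de(res, 1.5, 0.01, base_mean_min = 10)
  expect_identical(de2$gene, "a")
})

test_that("FDR is controlled on all-null tables", {
  grp <- rep(c("a", "b"), each = 3)
  frac <- vapply(1:8, function(s) {
    set.seed(s)
    g <- 300
    cts <- matrix(rnbinom(g * 6, mu = 500, size = 20), g,
                  dimnames = list(sprintf("g%03d", 1:g), NULL))
    sf <- size_factors(cts)
    al <- estimate_dispersion(cts, sf, grp)
    res <- nb_wald(cts, grp, sf, al, "b", "a")
    res$padj <- adjust_bh(res$p)
    mean(res$padj < 0.01, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(frac), 0.01)
})
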