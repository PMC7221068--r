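---
title: "Measuring transcriptional shock in interspecies hybrids: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transcriptional shock in interspecies hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

A newly formed interspecies hybrid carries two diverged genomes in one
nucleus. If the parental regulatory systems interfere, many genes should be
misregulated relative to their parental levels ("genomic shock"); if each
parental modulon keeps acting on its own sub-genome, expression should be
inherited. `hybridshock` implements the measurement framework for
distinguishing these outcomes in a diploid hybrid with diploid parents,
profiled in replicate at two temperatures so the hybridization effect can be
benchmarked against an ordinary environmental stress. All stages run on
synthetic data with known per-gene ground truth, which is what the test suite
exercises.

## The count model and the Wald test

Counts are negative binomial, `Var(K) = mu + alpha mu^2` (NB2). For a
two-group contrast, the reported effect is

```
l2fc = log2( mean_s(K_gs / f_gs | s in numerator)
           / mean_s(K_gs / f_gs | s in denominator) )
```

where `f_gs` are normalization factors. We use the ratio of group means of
normalized counts rather than an offset-GLM MLE deliberately: the package
guarantees *exact* normalization equivariance (multiplying one sample's
counts and factors by a constant changes no fold change) and exact contrast
antisymmetry, neither of which an IRLS fit with offsets delivers, because
rescaling a sample changes its likelihood weight. The standard error follows
from the NB variance by the delta method,

```
Var(log q_j) ~ (1/n_j^2) sum_s 1/(q_j f_gs)  +  alpha_g / n_j ,
```

and the Wald statistic `l2fc/se` is referred to a t distribution (below).
Genes with all-zero counts get `p = 1`; a group mean of exactly zero receives
a 0.5 pseudo-count and the gene is flagged `zero_group`. For designs beyond
two groups (the allele x temperature interaction), a full NB log-link GLM is
fitted by Newton iterations on the expected Fisher information
(`nb_wald_coef()`).

### Dispersion estimation

Per gene, a method-of-moments estimate on normalized counts,
`alpha = max((s2 - mu)/mu^2, 1e-8)` with the within-group variance pooled
across design groups, is shrunk on the log scale (weight 0.5 by default;
weight 0 gives the pure MoM estimator) toward a log-log linear
mean-dispersion trend fitted across genes. Two small-sample corrections
matter at 2-3 replicates:

* the log of a variance estimate with `df` degrees of freedom underestimates
  the true log variance by `digamma(df/2) - log(df/2)` (Jensen); without this
  correction the blended dispersions are biased low and the test is
  anti-conservative (measured type-I error 0.093 instead of ~0.05 at 3v3);
* genes whose raw estimate sits more than twice the *sampling* noise
  (`sqrt(trigamma(df/2))`) above the trend are genuine high-dispersion genes
  and keep their gene-wise estimate — shrinking them manufactures false
  positives with large apparent fold changes.

### Why a t reference instead of the normal

With plug-in dispersions estimated from 4-8 residual degrees of freedom, the
Wald statistic has noticeably heavier tails than normal, and the extreme tail
is exactly where `padj < 0.01` calls live. The statistic is therefore
referred to a t distribution whose degrees of freedom match the information
content of the blended dispersion estimate: blending log-dispersions with a
(nearly noiseless) trend at weight `w` scales their sampling variance by
`(1-w)^2`, so the effective df solves
`trigamma(df_eff/2) = (1-w)^2 trigamma(df/2)` (about 13 for 3v3 at
`w = 0.5`). Measured on the synthetic world, this yields type-I error 0.050
at nominal 0.05, all-null FDR-call fractions well under 0.01, and power 0.92
for designed |L2FC| = 3 effects at `mu >= 500`, `alpha <= 0.1` — while null
designs produce empty call sets in 20/20 seeds. A plain normal reference
remains available (`t_df = Inf`).

### Normalization regimes

* `library_size`: median-of-ratios size factors over genes positive in all
  samples, rescaled to geometric mean 1.
* `length_and_library`: allele-length-style factors times size factors
  computed on length-corrected counts — used for between-species contrasts,
  where ortholog lengths differ and would otherwise masquerade as expression
  differences.
* `allele_length_only`: `lengths / exp(rowMeans(log(lengths)))`, i.e. each
  gene's length divided by its row geometric mean, and **no** library
  component: within-hybrid allele columns come from the same library, so any
  depth correction would be wrong. Per gene, the factors multiply to 1 across
  samples by construction.

Calling thresholds are `|l2fc| > 1.5` and `padj < 0.01`, both strict, for
expression; `|l2fc| > 1`, `padj < 0.01` for promoter accessibility; the
relaxed filter (`|l2fc| > 1`, `padj < 0.05`, optionally mean normalized
expression > 10) is available for sensitivity analyses. BH is used for
multiplicity throughout.

## Contrast design, inheritance and scenarios

The four families fix sign conventions and normalization: parents =
log2(A/B) with length-and-library factors; homeologs = log2(alleleA/alleleB)
with allele-length-only factors; backgrounds = log2(hybrid/parent);
temperature = log2(cold/warm). Inheritance classification intersects the
parents and homeologs DE sets per ortholog pair: same-direction intersection
= `inherited_ASE`; homeolog-only = `acquired_ASE`; parents-only =
`attenuated`; neither = `conserved`. Pairs DE in both sets with *opposite*
directions do not satisfy the same-direction rule, are classified
`acquired_ASE`, and carry a `reversed` flag. The modulon scenarios are then
`scenario_i = (conserved + inherited)/N` (no crosstalk),
`scenario_ii = attenuated/N` (blending), `scenario_iii = acquired/N` (novel
divergence, the actual shock).

Temperature-dependent ASE is an allele x temperature interaction Wald test
in the NB GLM, not a set difference between per-temperature ASE lists: set
differences conflate threshold noise at the calling boundary with true
condition dependence. The set-difference variant can be assembled from
per-temperature `run_contrast()` calls if wanted.

## Read assignment and cross-mapping

A k-mer index (canonical over strands, k = 21 by default, odd so no k-mer is
its own reverse complement) over the concatenated two-genome reference
replaces an aligner: each read votes with its k-mers, and the label goes to
the sub-genome with more *exclusive* k-mer votes when the margin reaches
`min_margin` (default 1); ties are `ambiguous`, never assigned — the
unique-mapping convention for allele-specific counting. At 20% divergence a
50 bp read practically always contains exclusive 21-mers, so cross-mapping
is negligible (measured 0 of 10000 reads per genome), while identical
genomes give 100% ambiguity; both limits are asserted in the tests, and an
exhaustive scanning oracle verifies the votes read by read. Reads are counted
into a gene when their inferred start lies within the gene body (closed
interval on GTF coordinates); ambiguous/unassigned reads are dropped, not
fractionally split.

## The synthetic world

The generator defaults are the package's stated world, chosen once:

* 2 chromosomes x 100 kb, 300 non-overlapping genes (200-600 bp), 3
  replicates — large enough for stable FDR behavior, seconds-scale to run;
* substitution-only divergence 0.2 (the coding-sequence divergence of the
  yeast species pair this design mirrors), applied by mutating an ancestral
  sequence independently per lineage at the rate that yields the requested
  pairwise mismatch fraction; no indels, so homology is positional and read
  truth-tracking is exact;
* designed effects of |log2 FC| = 3 for affected genes, split +-e/2 around
  the baseline so each contrast recovers e; category fractions conserved
  0.88 / inherited 0.04 / attenuated 0.05 / acquired 0.03 (scenario
  fractions 0.92/0.05/0.03);
* baseline means log-uniform in [500, 5000]; per-gene NB dispersion
  log-uniform in [0.01, 0.3] — a modeling choice, no empirical dispersion
  distribution is asserted;
* ortholog/allele length ratios log-uniform in [0.8, 1.25], so length-aware
  normalization is genuinely exercised;
* library depth factors log-uniform in [0.7, 1.4]; hybrid allele columns
  share their replicate's depth factor;
* ATAC: peaks centered on promoters, width 300 bp, replicate coordinate
  jitter +-20 bp with ~5% score noise, background-specific peaks drawn from
  a lower score distribution (mean 350 vs 600, sd 120) — mirroring the
  empirical observation that condition-specific peaks tend to be weak calls.

What a green test does establish: correct arithmetic, calibration and
recovery of designed effects under the NB model with independent counts.
What it does not: robustness to features real data have and this world does
not — transcript structure (introns/isoforms), sequencing quality variation,
correlated counts, mappability artifacts, polymorphism within strains, or
dispersion heterogeneity beyond the sampled range.

Seeds are explicit everywhere; `derive_seed()` maps a pipeline master seed
to stage seeds by fixed offsets, and identical configurations reproduce
byte-identical TSV outputs.

## Chromatin occupancy and affinity

Replicate consensus merges overlapping peaks (>= 1 shared base) into their
union extent and keeps those supported by at least `min_reps = 2` of 3
replicates — the exact replicate rule of the original occupancy analysis is
not stated, so 2-of-3 is the package's choice, configurable. The
parent/hybrid partition counts each side against the other with the same
>= 1 bp overlap criterion (also configurable), so
`consensus_from_parent + parent_specific = |parent|` always. Score
comparisons use the two-sided Wilcoxon rank-sum with normal approximation,
ties and continuity correction; the narrowPeak column-5 score stands in for
the (undefined) plotted peak score. Promoters extend up to 1 kb upstream of
each gene's 5' end, truncated at neighboring gene bodies or chromosome
borders and never overlapping any gene body; zero-length promoters are
emitted but excluded from counting. Promoter accessibility uses summed
coverage as the read-count proxy (real fragment counting needs BAMs, out of
scope; real-mode users can supply counts directly) and reuses the NB engine
with promoter-length factors. Peak-to-gene links require promoter overlap
(>= 1 bp) and distance <= 1 kb, keeping the nearest gene per strand.

## Numerical and presentation choices

* Percentages in rendered reports are truncated (floor), not rounded to
  nearest: truncation reproduces the conventional presentation of every
  overlap fraction the report mirrors (e.g. 3091/3492 renders as 88%);
  raw fractions are kept in the TSVs.
* Dispersion floor 1e-8; Newton steps damped to +-5 with coefficients
  clamped at +-50 (natural log) so separated fits degrade gracefully and are
  flagged per gene instead of failing the pipeline.
* BH is implemented as the literal step-up with monotonicity enforcement;
  NAs are excluded from the multiplicity count and returned NA.
* Zero-read cross-mapping inputs report `NA` rates with a
  `rates_defined = FALSE` flag rather than propagating NaN.

## Known limitations

* At 3 replicates and strict `padj < 0.01`, genes at the top of the default
  dispersion range (alpha near 0.3) are near the detection floor for the
  allele x temperature interaction: recovery of |l2fc| = 3 interactions is
  ~9/10 when alpha <= 0.1 but drops (and occasional extreme-tail false
  positives appear) when the per-gene variance must be estimated at
  alpha ~ 0.3. This is a fundamental small-n limit, not an implementation
  artifact; the tests pin the alpha <= 0.1 regime.
* The k-mer assigner is a desk-scale stand-in for an aligner: no splicing,
  soft-clipping, or quality awareness; real-data mode bypasses it by
  consuming count tables.
* `run_pipeline()`'s differential-accessibility stage simulates promoter
  pair counts directly (coverage-level simulation of both sub-genomes within
  one hybrid library is not modeled).
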