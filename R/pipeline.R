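#' Build a validated pipeline configuration
#'
#' The defaults describe the synthetic "stated world" the pipeline is tested
#' against: a 2 x 100 kb genome pair at 20% divergence carrying 300 genes, a
#' four-category effect design with |log2 FC| = 3 for affected genes, three
#' replicates at two temperatures, and replicate ATAC peak sets with an 88%
#' shared fraction. Unknown keys are rejected by name.
#'
#' @param ... Overrides for any default key (see Details in the package
#'   vignette); nested values are supplied as complete sub-lists.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_chrom = 2L, chrom_len = 100000L, n_genes = 300L, divergence = 0.2,
    fractions = c(conserved = 0.88, inherited_ASE = 0.04,
                  attenuated = 0.05, acquired_ASE = 0.03),
    effect = 3, baseline_range = c(500, 5000),
    dispersion_range = c(0.01, 0.3),
    n_temp_ase = 2L, temp_fraction = 0.1,
    n_reps = 3L,
    l2fc_min = 1.5, padj_max = 0.01,
    k = 21L, read_len = 50L, n_reads = 10000L, error_rate = 0,
    min_margin = 1L,
    atac_n_peaks = 200L, atac_shared_fraction = 0.88, atac_jitter = 10L,
    atac_peak_width = 300L, atac_min_reps = 2L,
    da_fraction = 0.025, da_effect = 2, da_depth = 1000,
    da_l2fc_min = 1, da_padj_max = 0.01,
    run_quant = TRUE, run_concordance = FALSE, run_atac = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  config <- modifyList(defaults, over)
  if (is.null(config$seed)) stop("configuration key 'seed' is required")
  for (key in c("l2fc_min", "padj_max", "da_l2fc_min", "da_padj_max",
                "effect")) {
    if (config[[key]] <= 0) stop("configuration key '", key,
                                 "' must be positive")
  }
  check_fraction(config$divergence, "divergence", 0, 0.5)
  check_fraction(config$atac_shared_fraction, "atac_shared_fraction")
  class(config) <- c("pipeline_config", "list")
  config
}

# NB-simulated promoter-pair accessibility counts: a small fraction of
# homeologous promoter pairs gets a designed accessibility shift
simulate_da_counts <- function(lens_A, lens_B, n_reps, depth, da_fraction,
                               effect, dispersion = 0.05, seed = 1) {
  set.seed(seed)
  n <- length(lens_A)
  n_da <- round(da_fraction * n)
  idx <- sample.int(n, n_da)
  l2fc <- numeric(n)
  l2fc[idx] <- sample(c(-1, 1), n_da, replace = TRUE) * effect
  len_geo <- sqrt(lens_A * lens_B)
  cols <- list()
  meta <- list()
  for (g in c("A", "B")) {
    lens <- if (g == "A") lens_A else lens_B
    sgn <- if (g == "A") -0.5 else 0.5   # positive effect = more open in B
    for (r in seq_len(n_reps)) {
      mu <- depth * (lens / 1000) * 2^(sgn * l2fc) * (lens / len_geo)
      cols[[paste0(g, "_r", r)]] <- rnbinom_safe(mu, rep(dispersion, n))
      meta[[paste0(g, "_r", r)]] <- g
    }
  }
  counts <- do.call(cbind, cols)
  lengths <- cbind(matrix(lens_A, n, n_reps), matrix(lens_B, n, n_reps))
  colnames(lengths) <- colnames(counts)
  list(counts = counts, lengths = lengths,
       group = unlist(meta), truth_l2fc = l2fc)
}

#' Run the whole synthetic pipeline and collect the summary report
#'
#' Stages run in dependency order: genome/design/count simulation,
#' cross-mapping quantification (optional counting-mode concordance), the
#' four contrast families at both temperatures with transcriptome distances,
#' ASE-inheritance classification and modulon-scenario quantification,
#' temperature-dependent ASE, and the ATAC occupancy/affinity stage with
#' expression integration. Rerunning with the same configuration reproduces
#' identical outputs; when `out_dir` is given every table is also written as
#' TSV with a header carrying the config hash, stage seed and package
#' version.
#'
#' @param config A [pipeline_config].
#' @param out_dir Optional output directory for TSV artifacts.
#' @param quiet Suppress progress messages.
#' @return A `hybridshock_report` list; see [render_report()].
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(unclass(config))
  say <- function(...) if (!quiet) message("[hybridshock] ", ...)
  t_stage <- function(expr) {
    t0 <- Sys.time()
    val <- force(expr)
    attr(val, "elapsed_s") <- as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs"))
    val
  }

  say("stage syndata: genomes, design, counts")
  world <- t_stage({
    gp <- generate_genome_pair(config$n_chrom, config$chrom_len,
                               config$n_genes, config$divergence,
                               seed = derive_seed(config$seed, "genome"))
    design <- make_effect_design(
      nrow(gp$orthologs), fractions = config$fractions,
      effect = config$effect, baseline_range = config$baseline_range,
      dispersion_range = config$dispersion_range,
      n_temp_ase = config$n_temp_ase, temp_fraction = config$temp_fraction,
      gene_ids = sub("^A_", "", gp$orthologs$gene_A),
      seed = derive_seed(config$seed, "design"))
    tab <- simulate_counts(design, n_reps = config$n_reps,
                           seed = derive_seed(config$seed, "counts"))
    list(genome = gp, design = design, table = tab)
  })

  crossmap <- NULL
  concordance <- NULL
  if (config$run_quant) {
    say("stage quant: cross-mapping")
    crossmap <- t_stage(crossmap_simulated(
      world$genome$genomes, read_len = config$read_len,
      n_reads = config$n_reads, error_rate = config$error_rate,
      k = config$k, min_margin = config$min_margin,
      seed = derive_seed(config$seed, "quant")))
    if (config$run_concordance) {
      say("stage quant: counting-mode concordance")
      concordance <- t_stage(run_concordance_stage(world$genome, config))
    }
  }

  say("stage contrasts: four families, two temperatures")
  fams <- t_stage(run_contrast_stage(world$table, config))

  say("stage inheritance: classification and scenarios")
  inh <- lapply(c(warm = "warm", cold = "cold"), function(tmp) {
    cls <- classify_inheritance(
      fams[[paste0("parents_", tmp)]]$de,
      fams[[paste0("homeologs_", tmp)]]$de,
      universe = world$design$gene_id)
    cls$scenarios <- quantify_modulon_scenarios(cls$calls)
    cls
  })

  tase <- temperature_dependent_ase(world$table, config$l2fc_min,
                                    config$padj_max)

  atac <- NULL
  if (config$run_atac) {
    say("stage atac: occupancy, affinity, integration")
    atac <- t_stage(run_atac_stage(world, fams, config))
  }

  report <- structure(list(
    meta = list(config = config, config_hash = hash, seed = config$seed,
                version = as.character(packageVersion("hybridshock"))),
    de_counts = summarize_de_counts(fams),
    distances = summarize_distances(fams),
    inheritance = inh,
    temp_ase = list(n = nrow(tase$de), genes = tase$de$gene,
                    result = tase$result),
    crossmap = crossmap,
    concordance = concordance,
    atac = atac,
    contrasts = fams,
    world = world
  ), class = "hybridshock_report")

  if (!is.null(out_dir)) write_report_tsvs(report, out_dir)
  report
}

run_contrast_stage <- function(table, config) {
  out <- list()
  for (tmp in c("warm", "cold")) {
    out[[paste0("parents_", tmp)]] <- run_contrast(
      table, contrast_spec("parents", temperature = tmp),
      config$l2fc_min, config$padj_max)
    out[[paste0("homeologs_", tmp)]] <- run_contrast(
      table, contrast_spec("homeologs", temperature = tmp),
      config$l2fc_min, config$padj_max)
    for (sp in c("A", "B")) {
      out[[paste0("backgrounds_", sp, "_", tmp)]] <- run_contrast(
        table, contrast_spec("backgrounds", species = sp,
                             temperature = tmp),
        config$l2fc_min, config$padj_max)
    }
  }
  for (sp in c("A", "B")) {
    out[[paste0("temperature_", sp)]] <- run_contrast(
      table, contrast_spec("temperature", species = sp,
                           background = "parent"),
      config$l2fc_min, config$padj_max)
  }
  out
}

run_concordance_stage <- function(gp, config) {
  idx_comb <- build_concat_index(gp$genomes, config$k)
  idx_A <- build_concat_index(list(A = gp$genomes$sequences_A), config$k)
  idx_B <- build_concat_index(list(B = gp$genomes$sequences_B), config$k)
  ann <- list(A = gp$annotation_A, B = gp$annotation_B)
  genes <- c(gp$annotation_A$gene_id, gp$annotation_B$gene_id)
  gene_species <- rep(c("A", "B"),
                      c(nrow(gp$annotation_A), nrow(gp$annotation_B)))
  comb <- sep <- NULL
  sample_species <- character(0)
  base_seed <- derive_seed(config$seed, "reads")
  for (sp in c("A", "B")) {
    gseq <- if (sp == "A") gp$genomes$sequences_A else gp$genomes$sequences_B
    idx_own <- if (sp == "A") idx_A else idx_B
    for (r in 1:3) {
      reads <- simulate_reads(gseq, config$n_reads, config$read_len,
                              config$error_rate, genome_label = sp,
                              seed = base_seed + 10L * r +
                                (if (sp == "B") 100L else 0L))
      c_comb <- count_reads(assign_reads(reads, idx_comb,
                                         config$min_margin), ann)
      c_sep <- count_reads(assign_reads(reads, idx_own, config$min_margin),
                           ann[sp])
      full_sep <- setNames(integer(length(genes)), genes)
      full_sep[names(c_sep)] <- c_sep
      comb <- cbind(comb, c_comb[genes])
      sep <- cbind(sep, full_sep)
      sample_species <- c(sample_species, sp)
    }
  }
  colnames(comb) <- colnames(sep) <- paste0(sample_species, "_r",
                                            c(1:3, 1:3))
  rownames(comb) <- rownames(sep) <- genes
  counting_concordance(comb, sep, gene_species, sample_species)
}

run_atac_stage <- function(world, fams, config) {
  gp <- world$genome
  promoters <- define_promoters(gp$annotation_A, gp$genomes$chrom_lengths)
  sim <- simulate_atac(promoters,
                       n_peaks = min(config$atac_n_peaks,
                                     sum(promoters$length > 0)),
                       shared_fraction = config$atac_shared_fraction,
                       n_reps = config$n_reps,
                       peak_width = config$atac_peak_width,
                       jitter = config$atac_jitter,
                       seed = derive_seed(config$seed, "atac"))
  parent_cons <- replicate_consensus(sim$parent, config$atac_min_reps)
  hybrid_cons <- replicate_consensus(sim$hybrid, config$atac_min_reps)
  part <- partition_peaksets(parent_cons, hybrid_cons)
  score_groups <- list(
    parent_specific = part$parent_specific$score,
    consensus = part$consensus_from_parent$score,
    hybrid_specific = part$hybrid_specific$score)
  scores <- if (all(lengths(score_groups) > 0)) {
    score_comparison(score_groups)
  } else NULL

  # homeologous promoter affinity analysis on simulated pair counts
  prom_ok <- promoters[promoters$length > 0, , drop = FALSE]
  set.seed(derive_seed(config$seed, "atac") + 13L)
  ratio <- runif_log(nrow(prom_ok), 0.8, 1.25)
  da_in <- simulate_da_counts(
    lens_A = prom_ok$length,
    lens_B = pmax(round(prom_ok$length * ratio), 1L),
    n_reps = config$n_reps, depth = config$da_depth,
    da_fraction = config$da_fraction, effect = config$da_effect,
    seed = derive_seed(config$seed, "atac") + 17L)
  rownames(da_in$counts) <- prom_ok$gene_id
  da <- differential_accessibility(
    da_in$counts, da_in$lengths, da_in$group,
    l2fc_min = config$da_l2fc_min, padj_max = config$da_padj_max)

  # integration: background-specific peaks vs backgrounds DE (species A warm)
  links <- assign_peaks_to_genes(
    rbind(part$parent_specific, part$hybrid_specific),
    gp$annotation_A, promoters)
  spec_names <- c(rep(-1L, nrow(part$parent_specific)),
                  rep(1L, nrow(part$hybrid_specific)))
  dir_map <- setNames(spec_names, c(part$parent_specific$name,
                                    part$hybrid_specific$name))
  linked <- links[!is.na(links$gene_id), , drop = FALSE]
  linked$access_direction <- dir_map[linked$peak]
  integ <- integrate_expression(linked, fams$backgrounds_A_warm$de)

  # DA vs homeolog expression: positive DA = more open in B = allele A lower
  da_links <- rbind(
    if (nrow(da$more_open))
      data.frame(gene_id = da$more_open$gene, access_direction = -1L),
    if (nrow(da$less_open))
      data.frame(gene_id = da$less_open$gene, access_direction = 1L))
  if (is.null(da_links)) {
    da_links <- data.frame(gene_id = character(0),
                           access_direction = integer(0))
  }
  da_integ <- integrate_expression(da_links, fams$homeologs_warm$de)

  list(simulation_truth = sim$truth, partition = part$counts,
       shared_fraction_estimate = estimate_shared_fraction(part$counts),
       scores = scores, da = da,
       da_counts = c(more_open = nrow(da$more_open),
                     less_open = nrow(da$less_open)),
       peak_links = links, integration = integ$concordance,
       da_integration = da_integ$concordance)
}

summarize_de_counts <- function(fams) {
  do.call(rbind, lapply(names(fams), function(nm) {
    data.frame(contrast = nm, family = fams[[nm]]$spec$family,
               n_de = nrow(fams[[nm]]$de), stringsAsFactors = FALSE)
  }))
}

summarize_distances <- function(fams) {
  do.call(rbind, lapply(names(fams), function(nm) {
    gm <- fams[[nm]]$group_means
    data.frame(contrast = nm,
               one_minus_rho = expression_distance(gm[, 1], gm[, 2]),
               stringsAsFactors = FALSE)
  }))
}

write_report_tsvs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- function(stage) {
    sprintf("hybridshock %s | config %s | seed %d | stage %s",
            report$meta$version, report$meta$config_hash,
            report$meta$seed, stage)
  }
  wr <- function(df, file, stage) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(paste0("# ", hdr(stage)), con)
    suppressWarnings(
      write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
    path
  }
  wr(report$de_counts, "de_counts.tsv", "contrasts")
  wr(report$distances, "distances.tsv", "contrasts")
  for (tmp in names(report$inheritance)) {
    wr(report$inheritance[[tmp]]$venn, paste0("venn_", tmp, ".tsv"),
       "inheritance")
    wr(data.frame(scenario = names(report$inheritance[[tmp]]$scenarios),
                  fraction = report$inheritance[[tmp]]$scenarios),
       paste0("scenarios_", tmp, ".tsv"), "inheritance")
    wr(report$inheritance[[tmp]]$calls, paste0("calls_", tmp, ".tsv"),
       "inheritance")
  }
  if (!is.null(report$crossmap)) {
    wr(report$crossmap, "crossmap.tsv", "quant")
  }
  if (!is.null(report$atac)) {
    wr(data.frame(key = names(report$atac$partition),
                  count = as.integer(report$atac$partition)),
       "atac_partition.tsv", "atac")
    wr(report$atac$da$result, "atac_da.tsv", "atac")
  }
  invisible(out_dir)
}
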