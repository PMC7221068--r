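#' Render a pipeline report as human-readable text
#'
#' Produces the summary tables in the presentation style of the study design:
#' DE counts per contrast family, transcriptome distances, directional Venn
#' counts with overlap percentages, modulon-scenario fractions labeled
#' (i)/(ii)/(iii), the peak partition with percentages, differential
#' accessibility counts and integration concordance. Percentages are
#' truncated to whole numbers ([format_percentage()]); raw fractions stay in
#' the TSV outputs. Zero denominators render as 0 rather than erroring.
#'
#' @param report A `hybridshock_report` from [run_pipeline()].
#' @return Character vector of report lines (also printed invisibly usable
#'   with [writeLines()]).
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "hybridshock_report"))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))

  add("hybridshock report (version ", report$meta$version, ")")
  add("config ", report$meta$config_hash, " | master seed ",
      report$meta$seed)
  add("")
  add("== Differential expression by contrast ==")
  for (i in seq_len(nrow(report$de_counts))) {
    add(sprintf("  %-22s %5d DE genes", report$de_counts$contrast[i],
                report$de_counts$n_de[i]))
  }
  add("")
  add("== Transcriptome distance (1 - Spearman rho) ==")
  for (i in seq_len(nrow(report$distances))) {
    add(sprintf("  %-22s %.4f", report$distances$contrast[i],
                report$distances$one_minus_rho[i]))
  }

  for (tmp in names(report$inheritance)) {
    inh <- report$inheritance[[tmp]]
    add("")
    add("== ASE inheritance (", tmp, ") ==")
    for (i in seq_len(nrow(inh$venn))) {
      v <- inh$venn[i, ]
      side <- if (v$direction == 1) "A-higher" else "B-higher"
      pct <- format_percentage(v$both, v$both + v$homeologs_only)
      add(sprintf(
        "  %-9s both=%d homeolog-only=%d parents-only=%d (inherited %d%%)",
        side, v$both, v$homeologs_only, v$parents_only, pct))
    }
    sc <- inh$scenarios
    add(sprintf(
      "  modulon scenarios: (i) %.4f  (ii) %.4f  (iii) %.4f",
      sc[["scenario_i"]], sc[["scenario_ii"]], sc[["scenario_iii"]]))
  }

  add("")
  add("== Temperature-dependent ASE ==")
  add("  genes with allele x temperature interaction: ",
      report$temp_ase$n)

  if (!is.null(report$crossmap)) {
    add("")
    add("== Cross-mapping ==")
    for (i in seq_len(nrow(report$crossmap))) {
      r <- report$crossmap[i, ]
      rate <- if (isTRUE(r$rates_defined))
        sprintf("cross_rate=%.5f ambiguous=%.4f", r$cross_rate,
                r$ambiguous_rate) else "rates undefined (no reads)"
      add(sprintf("  genome %s: n=%d %s", r$source, r$n_reads, rate))
    }
  }

  if (!is.null(report$concordance)) {
    add("")
    add("== Counting-mode concordance ==")
    for (i in seq_len(nrow(report$concordance$rho))) {
      r <- report$concordance$rho[i, ]
      add(sprintf("  species %s: Spearman rho (mean) = %.5f", r$species,
                  r$rho_mean))
    }
    add("  genes flagged by relaxed DE filter: ",
        length(report$concordance$de_genes))
  }

  if (!is.null(report$atac)) {
    p <- report$atac$partition
    add("")
    add("== ATAC occupancy ==")
    add(sprintf(
      "  parent: %d peaks, %d consensus (%d%%), %d parent-specific",
      p[["parent"]], p[["consensus_from_parent"]],
      format_percentage(p[["consensus_from_parent"]], p[["parent"]]),
      p[["parent_specific"]]))
    add(sprintf(
      "  hybrid: %d peaks, %d consensus (%d%%), %d hybrid-specific",
      p[["hybrid"]], p[["consensus_from_hybrid"]],
      format_percentage(p[["consensus_from_hybrid"]], p[["hybrid"]]),
      p[["hybrid_specific"]]))
    if (!is.null(report$atac$scores)) {
      for (i in seq_len(nrow(report$atac$scores))) {
        s <- report$atac$scores[i, ]
        add(sprintf("  score %s vs %s: Wilcoxon p = %.3g", s$group1,
                    s$group2, s$p_value))
      }
    }
    add("== ATAC affinity (homeologous promoters) ==")
    add(sprintf("  more open in B: %d | less open: %d",
                report$atac$da_counts[["more_open"]],
                report$atac$da_counts[["less_open"]]))
    ic <- report$atac$integration
    add(sprintf(
      "  specific peaks vs expression: same=%d opposite=%d no-DE=%d",
      ic[["same_direction"]], ic[["opposite_direction"]], ic[["no_de"]]))
  }
  ln
}

#' @export
print.hybridshock_report <- function(x, ...) {
  writeLines(render_report(x))
  invisible(x)
}

#' Overlap percentage for one direction of the inheritance Venn
#'
#' Convenience wrapper used in reporting: the percentage of imbalanced
#' homeologs whose imbalance is inherited, i.e.
#' `both / (both + homeolog_only)` truncated to a whole percentage.
#'
#' @param both Pairs DE in both comparisons with the same direction.
#' @param homeolog_only Pairs DE only between homeologs.
#' @return Integer percentage.
#' @export
venn_overlap_percentage <- function(both, homeolog_only) {
  format_percentage(both, both + homeolog_only)
}
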