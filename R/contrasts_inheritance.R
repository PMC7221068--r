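#' Classify ASE inheritance from the parental and homeolog DE sets
#'
#' Each one-to-one ortholog pair is placed in exactly one category by
#' intersecting the between-parent DE set with the within-hybrid (homeolog)
#' DE set:
#'
#' * `inherited_ASE`: DE in both comparisons with the SAME direction — the
#'   hybrid inherited a pre-existing parental difference;
#' * `acquired_ASE`: homeolog-only DE, or DE in both with OPPOSITE directions
#'   (the same-direction rule excludes sign flips from the inherited
#'   intersection; flipped pairs are additionally flagged `reversed`);
#' * `attenuated`: parents-only DE — an interspecies difference that vanished
#'   in the hybrid;
#' * `conserved`: DE in neither.
#'
#' Pairs outside `universe` are not classified. Directional Venn counts are
#' reported per direction (`1`: species/allele A higher; `-1`: B higher) in
#' the layout (both, homeolog-only, parents-only).
#'
#' @param parents_de DE calls (`data.frame` with `gene`, `direction`) from the
#'   parents contrast, genes named by ortholog-pair identifier.
#' @param homeolog_de DE calls from the homeologs contrast, same identifiers.
#' @param universe Character vector of all tested ortholog-pair identifiers.
#' @return List with `calls` (`data.frame(pair, category, parent_direction,
#'   homeolog_direction, reversed)`) and `venn`
#'   (`data.frame(direction, both, homeologs_only, parents_only)`).
#' @export
classify_inheritance <- function(parents_de, homeolog_de, universe) {
  for (nm in c("parents_de", "homeolog_de")) {
    de <- get(nm)
    if (nrow(de) && !all(de$gene %in% universe)) {
      stop(nm, " contains genes outside the universe")
    }
    if (nrow(de) && any(is.na(de$direction))) {
      stop("direction missing for a DE gene in ", nm)
    }
  }
  p_dir <- setNames(parents_de$direction, parents_de$gene)
  h_dir <- setNames(homeolog_de$direction, homeolog_de$gene)

  in_p <- universe %in% names(p_dir)
  in_h <- universe %in% names(h_dir)
  pd <- ifelse(in_p, p_dir[universe], 0L)
  hd <- ifelse(in_h, h_dir[universe], 0L)

  category <- rep("conserved", length(universe))
  category[in_p & !in_h] <- "attenuated"
  category[!in_p & in_h] <- "acquired_ASE"
  category[in_p & in_h & pd == hd] <- "inherited_ASE"
  category[in_p & in_h & pd != hd] <- "acquired_ASE"
  reversed <- in_p & in_h & pd != hd

  calls <- data.frame(
    pair = universe, category = category,
    parent_direction = ifelse(in_p, pd, NA_integer_),
    homeolog_direction = ifelse(in_h, hd, NA_integer_),
    reversed = reversed, stringsAsFactors = FALSE)

  venn <- do.call(rbind, lapply(c(1L, -1L), function(d) {
    data.frame(
      direction = d,
      both = sum(in_p & in_h & pd == d & hd == d),
      homeologs_only = sum(hd == d & in_h & !(in_p & pd == d)),
      parents_only = sum(pd == d & in_p & !(in_h & hd == d)))
  }))
  list(calls = calls, venn = venn)
}

#' Quantify the three modulon regulatory scenarios
#'
#' After hybridization the regulatory machineries ("modulons") of the two
#' parental species can (i) act on their own sub-genome with no crosstalk, so
#' parental expression levels are inherited; (ii) blend, attenuating
#' interspecies differences; or (iii) preferentially target one allele,
#' creating divergence absent in the parents — the actual transcriptomic
#' shock. The scenarios map onto the inheritance categories:
#' `scenario_i = (conserved + inherited_ASE)/N`,
#' `scenario_ii = attenuated/N`, `scenario_iii = acquired_ASE/N`.
#'
#' @param calls The `calls` data frame from [classify_inheritance()] (or the
#'   whole list).
#' @return Named numeric vector `(scenario_i, scenario_ii, scenario_iii)`;
#'   the fractions sum to 1.
#' @export
quantify_modulon_scenarios <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) calls <- calls$calls
  n <- nrow(calls)
  if (n == 0) stop("empty universe")
  tab <- table(factor(calls$category,
                      levels = c("conserved", "inherited_ASE",
                                 "attenuated", "acquired_ASE")))
  c(scenario_i = unname((tab[["conserved"]] + tab[["inherited_ASE"]]) / n),
    scenario_ii = unname(tab[["attenuated"]] / n),
    scenario_iii = unname(tab[["acquired_ASE"]] / n))
}
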