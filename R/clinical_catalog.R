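# clinical_catalog: mutational-significance tiers from three evidence
# factors, the Tier X rule, clinical-evidence levels, pathway mapping

TIER_LEVELS <- c("Tier1", "Tier2", "Tier3", "Other", "TierX", "Unranked")

#' Mutational-significance tier from the three evidence factors
#'
#' The tier of a catalogued amino-acid change is determined by three
#' boolean evidence factors: (1) recurrence among driver-gene mutations,
#' (2) pathogenic assertion in ClinVar, and (3) positive selection by the
#' dN/dS ratio. Tier 1 requires factors 1 and 2 together; Tier 2 any two
#' factors otherwise; Tier 3 exactly one factor; changes with no factor are
#' ranked Other. Vectorised over the inputs.
#'
#' @param f_recurrent_driver,f_clinvar_pathogenic,f_dnds_selection logical
#'   (or 0/1) vectors of equal length.
#' @return Character vector in `{"Tier1", "Tier2", "Tier3", "Other"}`.
#' @export
tier_from_factors <- function(f_recurrent_driver, f_clinvar_pathogenic,
                              f_dnds_selection) {
  f1 <- as.logical(f_recurrent_driver)
  f2 <- as.logical(f_clinvar_pathogenic)
  f3 <- as.logical(f_dnds_selection)
  if (anyNA(c(f1, f2, f3))) {
    stop_alltriage("evidence factors must be defined (no missing values)",
                   "alltriage_validation_error")
  }
  n_true <- f1 + f2 + f3
  ifelse(f1 & f2, "Tier1",
         ifelse(n_true >= 2, "Tier2",
                ifelse(n_true == 1, "Tier3", "Other")))
}

# tier a census record itself carries: its label "other" overrides the
# factor-derived tier (the catalogue's own ranking is authoritative)
census_record_tier <- function(census) {
  tiers <- tier_from_factors(census$f_recurrent_driver,
                             census$f_clinvar_pathogenic,
                             census$f_dnds_selection)
  ifelse(tolower(census$cmc_label) == "other", "Other", tiers)
}

#' Classify one protein change against the mutation census
#'
#' Looks a parsed protein change up in the mutation-census catalogue and
#' returns its tier together with the match basis:
#' \itemize{
#'   \item exact (gene, position, ref, alt) match: the tier derived from
#'     that record's evidence factors — unless the record is labelled
#'     `"other"` while the position also carries a Tier 1–3 record, in
#'     which case the change is Tier X;
#'   \item no exact match, but the same (gene, position) holds at least one
#'     Tier 1–3 record: Tier X (an uncatalogued change at a position with
#'     tiered evidence);
#'   \item otherwise: Unranked.
#' }
#' Frameshift changes (`aa_alt == "fs"`) never match exactly; they can
#' still acquire Tier X through position matching.
#'
#' @param gene gene symbol.
#' @param aa_ref,aa_pos,aa_alt parsed protein-change components
#'   ([parse_protein_change()]).
#' @param census `mutation_census` catalogue from [read_catalog()].
#' @return A list with `tier` (one of Tier1, Tier2, Tier3, Other, TierX,
#'   Unranked), `basis` (`"exact"`, `"position"` or `"none"`), and
#'   `cmc_label` (the matched record's label, NA otherwise).
#' @details If catalogue records at the queried position disagree with the
#'   query's reference amino acid, a warning is raised and the records are
#'   still used for position matching (isoform numbering differences are a
#'   common cause).
#' @export
classify_variant_tier <- function(gene, aa_ref, aa_pos, aa_alt, census) {
  unranked <- list(tier = "Unranked", basis = "none", cmc_label = NA_character_)
  if (is.na(gene) || is.na(aa_pos)) return(unranked)
  at_pos <- census[census$gene == gene & census$aa_pos == aa_pos, ,
                   drop = FALSE]
  if (!nrow(at_pos)) return(unranked)
  if (!is.na(aa_ref) && any(at_pos$aa_ref != aa_ref)) {
    warning(sprintf(
      "%s position %d: query reference '%s' conflicts with catalogue ('%s'); treated as position match",
      gene, aa_pos, aa_ref,
      paste(unique(at_pos$aa_ref[at_pos$aa_ref != aa_ref]), collapse = ",")),
      call. = FALSE)
  }
  rec_tiers <- census_record_tier(at_pos)
  pos_tiered <- any(rec_tiers %in% c("Tier1", "Tier2", "Tier3"))
  exact_idx <- which(at_pos$aa_ref == aa_ref & at_pos$aa_alt == aa_alt &
                       aa_alt != "fs")
  if (length(exact_idx)) {
    rec <- at_pos[exact_idx[1], , drop = FALSE]
    if (tolower(rec$cmc_label) == "other" && pos_tiered) {
      return(list(tier = "TierX", basis = "exact", cmc_label = rec$cmc_label))
    }
    return(list(tier = tier_from_factors(rec$f_recurrent_driver,
                                         rec$f_clinvar_pathogenic,
                                         rec$f_dnds_selection),
                basis = "exact", cmc_label = rec$cmc_label))
  }
  if (pos_tiered) {
    return(list(tier = "TierX", basis = "position", cmc_label = NA_character_))
  }
  unranked
}

#' Clinical-evidence level of a gene
#'
#' Levels follow the OncoKB-style 1–4 scale: FDA-recognised biomarker
#' (level 1), standard-care biomarker (level 2), compelling clinical
#' evidence (level 3), compelling biological evidence (level 4), collapsed
#' across the diagnostic / prognostic / therapeutic categories. The
#' strongest (minimum) level across categories is returned together with
#' the categories attaining it.
#'
#' @param gene gene symbol.
#' @param clinical_levels `clinical_levels` catalogue from [read_catalog()].
#' @return A list with `level` (integer 1–4, or NA when the gene is not in
#'   the catalogue) and `categories` (character vector, sorted).
#' @export
assign_clinical_level <- function(gene, clinical_levels) {
  rows <- clinical_levels[clinical_levels$gene == gene, , drop = FALSE]
  if (!nrow(rows)) return(list(level = NA_integer_, categories = character(0)))
  lv <- min(rows$level)
  list(level = as.integer(lv),
       categories = sort(unique(rows$category[rows$level == lv])))
}

#' Targetable-pathway membership of a gene
#'
#' @param gene gene symbol.
#' @param pathways `pathways` catalogue from [read_catalog()].
#' @return Character vector of pathway labels (sorted; empty when the gene
#'   has no catalogued pathway).
#' @export
map_pathway <- function(gene, pathways) {
  sort(unique(pathways$pathway[pathways$gene == gene]))
}

#' Classify every variant in a set: tier, level, pathway
#'
#' Applies [classify_variant_tier()], [assign_clinical_level()] and
#' [map_pathway()] to each distinct (gene, protein change) in a variant
#' set. Variants whose protein change is absent or unparseable are
#' Unranked with basis `"none"`.
#'
#' @param vs a [variant_set()] (typically the survivors of [run_cascade()]).
#' @param census,clinical_levels,pathways catalogues from [read_catalog()].
#' @return A data.frame of class `tier_calls`, one row per distinct
#'   (gene, protein_change): columns `gene`, `protein_change`, `aa_ref`,
#'   `aa_pos`, `aa_alt`, `tier`, `basis`, `level`, `categories`
#'   (`;`-collapsed), `pathway` (`;`-collapsed), ordered by (gene, aa_pos).
#' @export
classify_variants <- function(vs, census, clinical_levels, pathways) {
  v <- vs$variants
  key <- paste(v$gene, v$protein_change, sep = "\r")
  keep <- !duplicated(key)
  u <- v[keep, c("gene", "protein_change", "aa_ref", "aa_pos", "aa_alt"),
         drop = FALSE]
  n <- nrow(u)
  tier <- character(n); basis <- character(n)
  level <- integer(n); categories <- character(n); pathway <- character(n)
  for (i in seq_len(n)) {
    tc <- classify_variant_tier(u$gene[i], u$aa_ref[i], u$aa_pos[i],
                                u$aa_alt[i], census)
    tier[i] <- tc$tier
    basis[i] <- tc$basis
    lv <- if (is.na(u$gene[i])) list(level = NA_integer_,
                                     categories = character(0))
          else assign_clinical_level(u$gene[i], clinical_levels)
    level[i] <- lv$level
    categories[i] <- paste(lv$categories, collapse = ";")
    pathway[i] <- if (is.na(u$gene[i])) "" else
      paste(map_pathway(u$gene[i], pathways), collapse = ";")
  }
  out <- data.frame(gene = u$gene, protein_change = u$protein_change,
                    aa_ref = u$aa_ref, aa_pos = u$aa_pos, aa_alt = u$aa_alt,
                    tier = tier, basis = basis, level = level,
                    categories = categories, pathway = pathway,
                    stringsAsFactors = FALSE)
  ord <- order(out$gene, out$aa_pos, out$protein_change, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tier_calls", "data.frame")
  out
}
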