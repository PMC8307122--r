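# filter_cascade: coding restriction -> control subtraction -> population
# allele-frequency filter, with an auditable per-stage trace

# default coding consequence vocabulary: non-synonymous substitutions plus
# the standard truncating classes
DEFAULT_CODING_CONSEQUENCES <- c(
  "missense_variant", "stop_gained", "stop_lost", "start_lost",
  "inframe_insertion", "inframe_deletion", "frameshift_variant",
  "splice_acceptor_variant", "splice_donor_variant")

#' Filter cascade configuration
#'
#' @param coding_consequences consequence terms that count as coding /
#'   protein-altering. Defaults to missense, nonsense (stop gained/lost),
#'   start loss, in-frame indels, frameshift, and essential splice-site
#'   classes.
#' @param af_population population label to filter on in the allele
#'   frequency catalogue (default `"LAT"`, Latino/Admixed American).
#' @param af_threshold frequency threshold as a fraction; variants with
#'   catalogue frequency strictly greater than this are removed (default
#'   0.05, i.e. "more than 5 percent"; a variant at exactly the threshold
#'   survives).
#' @param match_mode `"allele"` (default) matches catalogue/control entries
#'   on the full (chrom, pos, ref, alt) key; `"position"` matches on
#'   (chrom, pos) only.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(coding_consequences = DEFAULT_CODING_CONSEQUENCES,
                          af_population = "LAT",
                          af_threshold = 0.05,
                          match_mode = c("allele", "position")) {
  match_mode <- match.arg(match_mode)
  if (!length(coding_consequences)) {
    stop_alltriage("coding_consequences must be non-empty",
                   "alltriage_validation_error")
  }
  if (!is.numeric(af_threshold) || af_threshold <= 0 || af_threshold >= 1) {
    stop_alltriage("af_threshold must lie strictly between 0 and 1",
                   "alltriage_validation_error")
  }
  structure(list(coding_consequences = coding_consequences,
                 af_population = af_population,
                 af_threshold = af_threshold,
                 match_mode = match_mode),
            class = "filter_config")
}

#' Restrict a variant set to coding consequences
#'
#' Keeps variants whose consequence term is in the coding vocabulary;
#' unannotated variants are removed along with non-coding classes.
#'
#' @param vs a [variant_set()].
#' @param coding_consequences character vector of consequence terms.
#' @return The filtered `variant_set`.
#' @export
restrict_coding <- function(vs,
                            coding_consequences = DEFAULT_CODING_CONSEQUENCES) {
  keep <- !is.na(vs$variants$consequence) &
    vs$variants$consequence %in% coding_consequences
  vs_subset(vs, keep)
}

#' Remove cohort variants observed in control samples
#'
#' A cohort variant is removed when the same allele key (or, in
#' `"position"` mode, any allele at the same site) has dosage >= 1 in any
#' control sample. No control allele-frequency threshold is applied: a
#' single carrier among the controls suffices for removal.
#'
#' @param vs cohort [variant_set()].
#' @param controls control [variant_set()].
#' @param match_mode `"allele"` or `"position"`; see [filter_config()].
#' @return The filtered `variant_set`.
#' @export
subtract_controls <- function(vs, controls,
                              match_mode = c("allele", "position")) {
  match_mode <- match.arg(match_mode)
  if (n_variants(vs) == 0) return(vs)
  carried <- if (n_variants(controls) == 0 || !length(samples(controls))) {
    logical(n_variants(controls))
  } else {
    rowSums(controls$geno >= 1, na.rm = TRUE) > 0
  }
  if (match_mode == "allele") {
    seen <- vs_keys(controls)[carried]
    keep <- !(vs_keys(vs) %in% seen)
  } else {
    seen <- position_key(controls$variants$chrom,
                         controls$variants$pos)[carried]
    keep <- !(position_key(vs$variants$chrom, vs$variants$pos) %in% seen)
  }
  vs_subset(vs, keep)
}

#' Remove variants common in a reference population
#'
#' Looks each variant up in the population allele-frequency catalogue and
#' removes it when its frequency in the named population is strictly
#' greater than the threshold. Variants with no catalogue entry for that
#' population are kept: absence from the catalogue is read as rarity, so
#' rare germline variants of potential relevance are retained.
#'
#' @param vs a [variant_set()].
#' @param af_catalog `population_af` catalogue from [read_catalog()].
#' @param population population label (e.g. `"LAT"`).
#' @param threshold removal threshold as a fraction (default 0.05; strict
#'   inequality, so a variant at exactly 5 percent survives).
#' @param match_mode `"allele"` or `"position"`; in position mode the
#'   maximum frequency across catalogued alleles at the site is used.
#' @return The filtered `variant_set`.
#' @export
filter_population_af <- function(vs, af_catalog, population = "LAT",
                                 threshold = 0.05,
                                 match_mode = c("allele", "position")) {
  match_mode <- match.arg(match_mode)
  if (n_variants(vs) == 0) return(vs)
  cat_pop <- af_catalog[af_catalog$population == population, , drop = FALSE]
  if (match_mode == "allele") {
    ckey <- variant_key(cat_pop$chrom, cat_pop$pos, cat_pop$ref, cat_pop$alt)
    af <- cat_pop$af[match(vs_keys(vs), ckey)]
  } else {
    ckey <- position_key(cat_pop$chrom, cat_pop$pos)
    qkey <- position_key(vs$variants$chrom, vs$variants$pos)
    af <- vapply(qkey, function(k) {
      hits <- cat_pop$af[ckey == k]
      if (length(hits)) max(hits) else NA_real_
    }, 0)
  }
  keep <- is.na(af) | af <= threshold
  vs_subset(vs, keep)
}

#' Run the full three-stage filter cascade
#'
#' Applies, in order: coding-consequence restriction, control subtraction,
#' and the population allele-frequency filter. The intent of the cascade is
#' to enrich for somatic mutations in a cohort sequenced without matched
#' normal tissue while retaining rare germline variants of potential
#' relevance.
#'
#' @param cohort cohort [variant_set()].
#' @param controls control [variant_set()].
#' @param af_catalog `population_af` catalogue from [read_catalog()].
#' @param config a [filter_config()].
#' @return A list of class `cascade_result` with elements `variants` (the
#'   surviving `variant_set`) and `trace` (a `filter_trace` data.frame with
#'   per-stage `n_in`, `n_removed`, `n_out`; stages chain so each stage's
#'   `n_out` is the next stage's `n_in`).
#' @export
run_cascade <- function(cohort, controls, af_catalog,
                        config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  n0 <- n_variants(cohort)
  s1 <- restrict_coding(cohort, config$coding_consequences)
  n1 <- n_variants(s1)
  s2 <- subtract_controls(s1, controls, config$match_mode)
  n2 <- n_variants(s2)
  s3 <- filter_population_af(s2, af_catalog, config$af_population,
                             config$af_threshold, config$match_mode)
  n3 <- n_variants(s3)
  trace <- data.frame(
    stage = c("restrict_coding", "subtract_controls", "filter_population_af"),
    n_in = c(n0, n1, n2),
    n_removed = c(n0 - n1, n1 - n2, n2 - n3),
    n_out = c(n1, n2, n3),
    stringsAsFactors = FALSE)
  class(trace) <- c("filter_trace", "data.frame")
  structure(list(variants = s3, trace = trace), class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result>\n")
  tr <- x$trace
  for (i in seq_len(nrow(tr))) {
    cat(sprintf("  %-22s %5d -> %5d  (removed %d)\n",
                tr$stage[i], tr$n_in[i], tr$n_out[i], tr$n_removed[i]))
  }
  invisible(x)
}
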