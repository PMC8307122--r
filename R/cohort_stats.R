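# cohort_stats: patient x variant carrier matrix, position aggregation
# (G12X-style), stratified carrier frequencies

#' Build the patient-by-variant carrier matrix
#'
#' Columns are distinct (gene, protein change) keys; a sample carries a key
#' when its dosage is >= 1 for any allele mapping to it. All samples in the
#' metadata appear as rows, so patients with no surviving variant
#' contribute all-false rows and the cohort denominator stays fixed.
#'
#' @param vs a [variant_set()] (typically cascade survivors).
#' @param metadata data.frame with columns `sample`, `status`
#'   (`"new-onset"` / `"relapse"`), `subtype`, `ethnicity`; one row per
#'   cohort sample.
#' @return An object of class `cohort_matrix`: list with `carriers`
#'   (samples x keys logical matrix), `keys` (data.frame: `key`, `gene`,
#'   `protein_change`, `aa_ref`, `aa_pos`) and `meta` (the metadata,
#'   sample-ordered as the matrix rows).
#' @export
build_matrix <- function(vs, metadata) {
  required <- c("sample", "status", "subtype", "ethnicity")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stop_alltriage(paste0("metadata missing columns: ",
                          paste(missing_cols, collapse = ", ")),
                   "alltriage_validation_error")
  }
  unknown <- setdiff(samples(vs), metadata$sample)
  if (length(unknown)) {
    stop_alltriage(paste0("samples in VCF absent from metadata: ",
                          paste(unknown, collapse = ", ")),
                   "alltriage_validation_error")
  }
  meta <- metadata[!duplicated(metadata$sample), , drop = FALSE]
  meta <- meta[order(meta$sample, method = "radix"), , drop = FALSE]
  rownames(meta) <- NULL
  v <- vs$variants
  has_key <- !is.na(v$gene) & !is.na(v$protein_change)
  kg <- v$gene[has_key]
  kp <- v$protein_change[has_key]
  kr <- v$aa_ref[has_key]
  ka <- v$aa_pos[has_key]
  klab <- paste(kg, kp)
  keep <- !duplicated(klab)
  keys <- data.frame(key = klab[keep], gene = kg[keep],
                     protein_change = kp[keep], aa_ref = kr[keep],
                     aa_pos = ka[keep], stringsAsFactors = FALSE)
  ord <- order(keys$gene, keys$aa_pos, keys$protein_change, method = "radix")
  keys <- keys[ord, , drop = FALSE]
  rownames(keys) <- NULL
  carriers <- matrix(FALSE, nrow = nrow(meta), ncol = nrow(keys),
                     dimnames = list(meta$sample, keys$key))
  if (any(has_key) && length(samples(vs))) {
    idx <- match(klab, keys$key)
    geno_key <- vs$geno[has_key, , drop = FALSE]
    for (r in seq_along(idx)) {
      carr <- !is.na(geno_key[r, ]) & geno_key[r, ] >= 1
      sm <- colnames(geno_key)[carr]
      carriers[sm, idx[r]] <- TRUE
    }
  }
  structure(list(carriers = carriers, keys = keys, meta = meta),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d sample(s) x %d variant key(s)\n",
              nrow(x$carriers), ncol(x$carriers)))
  cat(sprintf("  carriers: %d TRUE entries\n", sum(x$carriers)))
  invisible(x)
}

#' Aggregate all changes at one amino-acid position
#'
#' Collapses every catalogued change at (gene, position) into a single
#' carrier group — the "G12X" convention for hotspot codons. A sample
#' carries the group when it carries any change at the position (nonsense
#' and frameshift changes included, counted once per sample).
#'
#' @param cm a [build_matrix()] result.
#' @param gene gene symbol.
#' @param aa_pos amino-acid position.
#' @return A `cohort_matrix` with one extra column labelled
#'   `"<gene> <ref><pos>X"` (e.g. `"KRAS G12X"`). Adding a group twice is a
#'   no-op.
#' @export
aggregate_position <- function(cm, gene, aa_pos) {
  sel <- which(cm$keys$gene == gene & !is.na(cm$keys$aa_pos) &
                 cm$keys$aa_pos == aa_pos)
  if (!length(sel)) {
    stop_alltriage(sprintf("no variant keys at %s position %d", gene, aa_pos),
                   "alltriage_validation_error")
  }
  ref <- cm$keys$aa_ref[sel]
  ref <- ref[!is.na(ref)][1]
  label <- sprintf("%s %s%dX", gene, if (is.na(ref)) "" else ref, aa_pos)
  if (label %in% colnames(cm$carriers)) return(cm)
  col <- rowSums(cm$carriers[, sel, drop = FALSE]) > 0
  cm$carriers <- cbind(cm$carriers, matrix(col, ncol = 1,
                                           dimnames = list(NULL, label)))
  cm$keys <- rbind(cm$keys,
                   data.frame(key = label, gene = gene,
                              protein_change = sprintf("%s%dX",
                                                       if (is.na(ref)) "" else ref,
                                                       aa_pos),
                              aa_ref = ref, aa_pos = aa_pos,
                              stringsAsFactors = FALSE))
  cm
}

#' Carrier frequency of a variant key, optionally stratified
#'
#' Counts carriers per stratum of a metadata attribute (or over the whole
#' cohort) and converts to percent. These are carrier (per-individual)
#' frequencies — the fraction of patients with at least one alternate
#' allele — not allele frequencies.
#'
#' @param cm a [build_matrix()] result.
#' @param key a column of the carrier matrix (variant key or aggregated
#'   position group).
#' @param stratify_by optional metadata column name (`"ethnicity"`,
#'   `"status"`, `"subtype"`).
#' @return data.frame with columns `key`, `stratum`, `n_carriers`,
#'   `n_total`, `percent`.
#' @export
carrier_frequency <- function(cm, key, stratify_by = NULL) {
  if (!key %in% colnames(cm$carriers)) {
    stop_alltriage(sprintf("unknown variant key '%s'", key),
                   "alltriage_validation_error")
  }
  col <- cm$carriers[, key]
  if (is.null(stratify_by)) {
    strata <- rep("all", nrow(cm$carriers))
  } else {
    if (!stratify_by %in% names(cm$meta)) {
      stop_alltriage(sprintf("unknown stratify attribute '%s'", stratify_by),
                     "alltriage_validation_error")
    }
    strata <- as.character(cm$meta[[stratify_by]])
    if (anyNA(strata)) {
      stop_alltriage(sprintf("stratify attribute '%s' undefined for some samples",
                             stratify_by),
                     "alltriage_validation_error")
    }
  }
  labels <- sort(unique(strata))
  out <- data.frame(
    key = key,
    stratum = labels,
    n_carriers = vapply(labels, function(s) sum(col[strata == s]), 0L),
    n_total = vapply(labels, function(s) sum(strata == s), 0L),
    stringsAsFactors = FALSE)
  out$percent <- 100 * out$n_carriers / out$n_total
  rownames(out) <- NULL
  out
}

#' Compare carrier frequencies between two strata
#'
#' Computes the fold difference in carrier percent between exactly two
#' strata (first over second, in the row order given) and returns the raw
#' 2x2 counts so a hypothesis test can be applied downstream if desired;
#' none is attached here, mirroring a descriptive frequency comparison.
#'
#' @param freq a two-row result of [carrier_frequency()].
#' @return A list of class `strata_comparison`: `fold` (NA when the
#'   denominator percent is 0), `undefined` (logical flag for that case),
#'   `counts` (2x2 matrix, carriers / non-carriers by stratum), and the
#'   input `freq`.
#' @export
compare_strata <- function(freq) {
  if (!is.data.frame(freq) || nrow(freq) != 2L) {
    stop_alltriage("compare_strata expects exactly two strata",
                   "alltriage_validation_error")
  }
  if (any(freq$n_total < 1)) {
    stop_alltriage("both strata must have n_total >= 1",
                   "alltriage_validation_error")
  }
  undefined <- freq$percent[2] == 0
  fold <- if (undefined) NA_real_ else freq$percent[1] / freq$percent[2]
  counts <- rbind(carriers = freq$n_carriers,
                  non_carriers = freq$n_total - freq$n_carriers)
  colnames(counts) <- freq$stratum
  structure(list(fold = fold, undefined = undefined, counts = counts,
                 freq = freq),
            class = "strata_comparison")
}

#' @export
print.strata_comparison <- function(x, ...) {
  cat("<strata_comparison>\n")
  cat(sprintf("  %s: %.1f%% (%d/%d)  vs  %s: %.1f%% (%d/%d)\n",
              x$freq$stratum[1], x$freq$percent[1], x$freq$n_carriers[1],
              x$freq$n_total[1],
              x$freq$stratum[2], x$freq$percent[2], x$freq$n_carriers[2],
              x$freq$n_total[2]))
  if (x$undefined) cat("  fold: undefined (zero denominator)\n")
  else cat(sprintf("  fold: %.2f\n", x$fold))
  invisible(x)
}
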