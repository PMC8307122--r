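# variant_io: VCF and catalogue ingestion, the variant_set container,
# and the tab-delimited report writer

#' Construct a variant set
#'
#' The package's central container: one row per (site, alternate allele)
#' with its functional annotation, plus a sample-by-variant dosage matrix.
#' Most users get one from [read_vcf()] or [generate_cohort()] rather than
#' calling this directly.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single allele), `gene`, `consequence`, `protein_change` (raw
#'   token or NA), `aa_ref`, `aa_pos`, `aa_alt` (parsed components, NA when
#'   absent or unparseable).
#' @param geno integer matrix, `nrow(variants)` rows by one column per
#'   sample, entries in `{0, 1, 2, NA}` (NA = missing genotype).
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(variants, geno) {
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                "protein_change", "aa_ref", "aa_pos", "aa_alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop_alltriage(paste0("variants is missing columns: ",
                          paste(missing_cols, collapse = ", ")),
                   "alltriage_validation_error")
  }
  if (!is.matrix(geno) || nrow(geno) != nrow(variants)) {
    stop_alltriage("geno must be a matrix with one row per variant",
                   "alltriage_validation_error")
  }
  if (is.null(colnames(geno)) && ncol(geno) > 0) {
    stop_alltriage("geno columns must be named by sample id",
                   "alltriage_validation_error")
  }
  if (nrow(variants) > 0) {
    if (any(variants$pos < 1, na.rm = TRUE)) {
      stop_alltriage("pos must be >= 1", "alltriage_validation_error")
    }
    if (any(grepl(",", variants$alt, fixed = TRUE))) {
      stop_alltriage("alt must be a single allele (split multi-allelics first)",
                     "alltriage_validation_error")
    }
    vals <- geno[!is.na(geno)]
    if (length(vals) && !all(vals %in% 0:2)) {
      stop_alltriage("dosages must lie in {0, 1, 2, NA}",
                     "alltriage_validation_error")
    }
  }
  rownames(variants) <- NULL
  structure(list(variants = variants, geno = geno), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d variant(s) x %d sample(s)\n",
              nrow(x$variants), ncol(x$geno)))
  if (nrow(x$variants)) {
    genes <- unique(x$variants$gene[!is.na(x$variants$gene)])
    cat("  genes:", paste(utils::head(genes, 8), collapse = ", "),
        if (length(genes) > 8) "..." else "", "\n")
  }
  if (ncol(x$geno)) {
    cat("  samples:", paste(utils::head(colnames(x$geno), 10), collapse = ", "),
        if (ncol(x$geno) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' Number of variants / sample ids of a variant set
#' @param x a `variant_set`.
#' @return `n_variants()`: integer; `samples()`: character vector.
#' @export
n_variants <- function(x) nrow(x$variants)

#' @rdname n_variants
#' @export
samples <- function(x) colnames(x$geno)

# allele keys for a variant_set
vs_keys <- function(x) {
  variant_key(x$variants$chrom, x$variants$pos, x$variants$ref, x$variants$alt)
}

# subset rows of a variant_set
vs_subset <- function(x, idx) {
  variant_set(x$variants[idx, , drop = FALSE],
              x$geno[idx, , drop = FALSE])
}

#' Read an annotated VCF into a variant set
#'
#' Reads a VCF v4.x file (single- or multi-sample), splits multi-allelic
#' records into one row per alternate allele, converts genotypes to dosage
#' (count of the alternate allele; phased and unphased treated identically),
#' and parses a pipe-delimited functional annotation from an INFO field.
#'
#' The annotation field (default `ANN`) is expected to hold one
#' `gene|consequence|protein_change` entry per alternate allele, comma
#' separated, in allele order — the compact form of VEP/SnpEff-style
#' annotations. Records without an annotation, or whose entry does not have
#' exactly three pipe-delimited sub-fields, are kept with consequence
#' `"unannotated"` (with a record-level warning for malformed entries).
#' Extra entries beyond the alternate-allele count are treated as alternate
#' transcript annotations: the allele keeps its first entry and the rest are
#' ignored.
#'
#' @param path path to a VCF file.
#' @param annotation_field name of the INFO sub-field carrying the
#'   annotation (default `"ANN"`).
#' @return A [variant_set()].
#' @export
read_vcf <- function(path, annotation_field = "ANN") {
  if (!file.exists(path)) {
    stop_alltriage(sprintf("VCF not found: %s", path), "alltriage_io_error")
  }
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, "##fileformat=VCF")) {
    stop_alltriage(sprintf(
      "malformed VCF %s: line 1 must be a ##fileformat=VCF header", path),
      "alltriage_parse_error")
  }
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) {
                  stop_alltriage(sprintf("malformed VCF %s: %s",
                                         path, conditionMessage(e)),
                                 "alltriage_parse_error")
                })
  fix <- v@fix
  n_rec <- nrow(fix)
  sample_ids <- character(0)
  gt <- NULL
  if (!is.null(v@gt) && ncol(v@gt) > 1) {
    sample_ids <- colnames(v@gt)[-1]
    gt <- v@gt[, -1, drop = FALSE]
  }
  ann_all <- if (n_rec) vcfR::extract.info(v, element = annotation_field)
             else character(0)

  rows <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    entries <- if (is.na(ann_all[i])) character(0)
               else strsplit(ann_all[i], ",", fixed = TRUE)[[1]]
    # per-sample allele calls for this record
    dosages <- matrix(NA_integer_, nrow = n_alt, ncol = length(sample_ids),
                      dimnames = list(NULL, sample_ids))
    if (length(sample_ids)) {
      calls <- gt[i, ]
      calls <- sub(":.*$", "", calls)  # GT is the first FORMAT field
      for (s in seq_along(calls)) {
        al <- strsplit(calls[s], "[/|]")[[1]]
        if (!length(al) || any(al == ".") || any(is.na(al))) next
        al <- suppressWarnings(as.integer(al))
        if (any(is.na(al))) next
        for (a in seq_len(n_alt)) dosages[a, s] <- sum(al == a)
      }
    }
    gene <- rep(NA_character_, n_alt)
    consequence <- rep("unannotated", n_alt)
    pchange <- rep(NA_character_, n_alt)
    for (a in seq_len(n_alt)) {
      if (a > length(entries)) next
      fields <- strsplit(entries[a], "|", fixed = TRUE)[[1]]
      # trailing empty sub-fields are dropped by strsplit; pad back
      n_pipes <- lengths(regmatches(entries[a], gregexpr("|", entries[a],
                                                         fixed = TRUE)))
      if (n_pipes + 1L != 3L) {
        warning(sprintf(
          "%s record %s:%s: annotation '%s' does not have 3 sub-fields; kept unannotated",
          basename(path), fix[i, "CHROM"], fix[i, "POS"], entries[a]),
          call. = FALSE)
        next
      }
      length(fields) <- 3L
      gene[a] <- if (!is.na(fields[1]) && nzchar(fields[1])) fields[1] else NA
      consequence[a] <- if (!is.na(fields[2]) && nzchar(fields[2]))
        fields[2] else "unannotated"
      pchange[a] <- if (!is.na(fields[3]) && nzchar(fields[3]))
        fields[3] else NA
    }
    rows[[i]] <- list(
      variants = data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts, gene = gene,
        consequence = consequence, protein_change = pchange,
        row.names = NULL, stringsAsFactors = FALSE),
      geno = dosages)
  }
  variants <- do.call(rbind, lapply(rows, `[[`, "variants"))
  geno <- do.call(rbind, lapply(rows, `[[`, "geno"))
  if (is.null(variants)) {
    variants <- data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           gene = character(0), consequence = character(0),
                           protein_change = character(0),
                           stringsAsFactors = FALSE)
    geno <- matrix(integer(0), nrow = 0, ncol = length(sample_ids),
                   dimnames = list(NULL, sample_ids))
  }
  parsed <- parse_protein_changes(variants$protein_change)
  variants <- cbind(variants, parsed)
  variant_set(variants, geno)
}

#' Merge variant sets from per-sample VCFs
#'
#' Takes the union of allele keys across sets and aligns dosages on a
#' common sample panel. A sample whose VCF does not list a site is assigned
#' dosage 0 there (single-sample VCFs enumerate carried variants only).
#' Annotation conflicts are resolved first-set-wins.
#'
#' @param sets list of [variant_set()] objects.
#' @return A single merged `variant_set`, rows ordered by (chrom, pos, ref,
#'   alt).
#' @export
merge_variant_sets <- function(sets) {
  sets <- sets[vapply(sets, n_variants, 1L) >= 0]  # keep empties for samples
  all_samples <- unique(unlist(lapply(sets, samples)))
  vtabs <- lapply(sets, function(s) s$variants)
  variants <- do.call(rbind, vtabs)
  if (is.null(variants) || nrow(variants) == 0) {
    empty <- sets[[1]]$variants[0, , drop = FALSE]
    return(variant_set(empty, matrix(integer(0), 0, length(all_samples),
                                     dimnames = list(NULL, all_samples))))
  }
  keys <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  keep <- !duplicated(keys)
  variants <- variants[keep, , drop = FALSE]
  ukeys <- keys[keep]
  geno <- matrix(0L, nrow = length(ukeys), ncol = length(all_samples),
                 dimnames = list(NULL, all_samples))
  for (s in sets) {
    if (!n_variants(s) || !length(samples(s))) next
    idx <- match(vs_keys(s), ukeys)
    for (sm in samples(s)) {
      d <- s$geno[, sm]
      upd <- !is.na(d)
      geno[idx[upd], sm] <- d[upd]
    }
  }
  ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt,
               method = "radix")
  variant_set(variants[ord, , drop = FALSE], geno[ord, , drop = FALSE])
}

#' Write a variant set as a VCF v4.2 file
#'
#' Emits plain-text VCF with the package's `gene|consequence|protein_change`
#' annotation in the named INFO field and GT-only genotypes. Output is
#' byte-deterministic for a given input, which the synthetic-data module
#' relies on.
#'
#' @param vs a [variant_set()].
#' @param path output file path.
#' @param annotation_field INFO field name (default `"ANN"`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, annotation_field = "ANN") {
  v <- vs$variants
  ord <- order(v$chrom, v$pos, v$ref, v$alt, method = "radix")
  v <- v[ord, , drop = FALSE]
  geno <- vs$geno[ord, , drop = FALSE]
  smp <- colnames(geno)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Functional annotation: gene|consequence|protein_change\">",
            annotation_field),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(smp)) c("FORMAT", smp)), collapse = "\t"))
  gt_string <- function(d) {
    if (is.na(d)) "./." else c("0/0", "0/1", "1/1")[d + 1L]
  }
  body <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    ann <- paste(
      ifelse(is.na(v$gene[i]), "", v$gene[i]),
      ifelse(is.na(v$consequence[i]), "", v$consequence[i]),
      ifelse(is.na(v$protein_change[i]), "", v$protein_change[i]),
      sep = "|")
    info <- paste0(annotation_field, "=", ann)
    cells <- c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS",
               info,
               if (length(smp)) c("GT", vapply(geno[i, ], gt_string, "")))
    body[i] <- paste(cells, collapse = "\t")
  }
  writeLines(c(header, body), path, sep = "\n")
  invisible(path)
}

# catalogue schemas: required columns and uniqueness keys
CATALOG_SCHEMAS <- list(
  population_af = list(
    cols = c("gene", "chrom", "pos", "ref", "alt", "population", "af"),
    key = c("chrom", "pos", "ref", "alt", "population")),
  mutation_census = list(
    cols = c("gene", "aa_ref", "aa_pos", "aa_alt", "f_recurrent_driver",
             "f_clinvar_pathogenic", "f_dnds_selection", "cmc_label"),
    key = c("gene", "aa_ref", "aa_pos", "aa_alt")),
  clinical_levels = list(
    cols = c("gene", "category", "level"),
    key = c("gene", "category")),
  pathways = list(
    cols = c("gene", "pathway"),
    key = c("gene", "pathway")),
  common_sites = list(
    cols = c("chrom", "pos", "ref", "alt"),
    key = c("chrom", "pos", "ref", "alt"))
)

#' Read and validate a catalogue snapshot table
#'
#' Catalogue tables are tab-delimited snapshots standing in for the live
#' annotation resources a production run would use: population allele
#' frequencies (gnomAD-style), per-amino-acid-change evidence factors
#' (COSMIC Cancer Mutation Census-style), gene clinical-evidence levels
#' (OncoKB-style), targetable-pathway membership, and common-variant site
#' lists (dbSNP-style). Lines starting with `#` are comments.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param kind one of `"population_af"`, `"mutation_census"`,
#'   `"clinical_levels"`, `"pathways"`, `"common_sites"`.
#' @return A validated data.frame of class `c("alltriage_catalog",
#'   "data.frame")` with attribute `kind`.
#' @details Validation is strict: missing required columns, duplicate keys,
#'   evidence factors outside \{0, 1\}, levels outside 1–4, categories
#'   outside \{diagnostic, prognostic, therapeutic\} and allele frequencies
#'   outside \[0, 1\] all raise a load error.
#' @export
read_catalog <- function(path, kind) {
  if (!kind %in% names(CATALOG_SCHEMAS)) {
    stop_alltriage(sprintf("unknown catalogue kind '%s'", kind),
                   "alltriage_load_error")
  }
  if (!file.exists(path)) {
    stop_alltriage(sprintf("catalogue not found: %s", path),
                   "alltriage_io_error")
  }
  schema <- CATALOG_SCHEMAS[[kind]]
  tab <- read_tsv(path)
  missing_cols <- setdiff(schema$cols, names(tab))
  if (length(missing_cols)) {
    stop_alltriage(sprintf("catalogue %s (%s) is missing columns: %s",
                           path, kind, paste(missing_cols, collapse = ", ")),
                   "alltriage_load_error")
  }
  key <- do.call(paste, c(tab[schema$key], sep = ":"))
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop_alltriage(sprintf("catalogue %s (%s) has duplicate keys: %s",
                           path, kind,
                           paste(utils::head(dup, 3), collapse = "; ")),
                   "alltriage_load_error")
  }
  if (kind == "mutation_census") {
    fcols <- c("f_recurrent_driver", "f_clinvar_pathogenic", "f_dnds_selection")
    for (fc in fcols) {
      if (!all(tab[[fc]] %in% c(0L, 1L))) {
        stop_alltriage(sprintf("catalogue %s: %s must be 0/1", path, fc),
                       "alltriage_load_error")
      }
    }
  }
  if (kind == "clinical_levels") {
    if (!all(tab$category %in% c("diagnostic", "prognostic", "therapeutic"))) {
      stop_alltriage(sprintf("catalogue %s: bad category value", path),
                     "alltriage_load_error")
    }
    if (!all(tab$level %in% 1:4)) {
      stop_alltriage(sprintf("catalogue %s: level must be 1-4", path),
                     "alltriage_load_error")
    }
  }
  if (kind == "population_af") {
    if (any(tab$af < 0 | tab$af > 1)) {
      stop_alltriage(sprintf("catalogue %s: af must be in [0, 1]", path),
                     "alltriage_load_error")
    }
  }
  structure(tab, kind = kind, class = c("alltriage_catalog", "data.frame"))
}

#' Write the per-patient classified variant table
#'
#' One row per (patient, variant) with gene, protein change, tier, clinical
#' level, pathway and disease status, in deterministic (gene, amino-acid
#' position, sample) order — the flat report the figures of a cohort study
#' are drawn from.
#'
#' @param classified data.frame with columns `sample`, `gene`,
#'   `protein_change`, `aa_pos`, `tier`, `level`, `pathway`, `status`.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_variant_table()] for the round-trip reader.
#' @export
write_variant_table <- function(classified, path) {
  required <- c("sample", "gene", "protein_change", "aa_pos", "tier",
                "level", "pathway", "status")
  missing_cols <- setdiff(required, names(classified))
  if (length(missing_cols)) {
    stop_alltriage(paste0("classified table missing columns: ",
                          paste(missing_cols, collapse = ", ")),
                   "alltriage_validation_error")
  }
  out <- classified[required]
  ord <- order(out$gene, out$aa_pos, out$sample, method = "radix")
  write_tsv(out[ord, , drop = FALSE], path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  tab <- read_tsv(path)
  tab$aa_pos <- as.integer(tab$aa_pos)
  tab
}
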