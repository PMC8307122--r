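# cli_report: end-to-end orchestration from a single config, level-grouped
# report tables, run manifest, and the accession-gated external-cohort hook

empty_variant_set <- function(sample_ids = character(0)) {
  planted_variant_set(
    data.frame(sample = character(0), gene = character(0),
               protein_change = character(0), consequence = character(0),
               stringsAsFactors = FALSE),
    sample_ids)
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop_alltriage(sprintf("config file not found: %s", config),
                     "alltriage_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  required <- c("cohort_vcfs", "metadata", "catalogs", "out_dir")
  missing_fields <- setdiff(required, names(config))
  if (length(missing_fields)) {
    stop_alltriage(paste0("config missing fields: ",
                          paste(missing_fields, collapse = ", ")),
                   "alltriage_config_error")
  }
  needed_catalogs <- c("population_af", "mutation_census", "clinical_levels",
                       "pathways")
  missing_cats <- setdiff(needed_catalogs, names(config$catalogs))
  if (length(missing_cats)) {
    stop_alltriage(paste0("config missing catalogue paths: ",
                          paste(missing_cats, collapse = ", ")),
                   "alltriage_config_error")
  }
  paths <- c(unlist(config$cohort_vcfs), unlist(config$control_vcfs),
             config$metadata, unlist(config$catalogs))
  gone <- paths[!file.exists(paths)]
  if (length(gone)) {
    stop_alltriage(paste0("config references missing files: ",
                          paste(gone, collapse = ", ")),
                   "alltriage_config_error")
  }
  config$filter <- config$filter %||% list()
  config$stratify <- config$stratify %||% "status"
  config$groups <- config$groups %||% list()
  config
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "alltriage_stage_error")) stop(e)
    stop_alltriage(sprintf("stage '%s' failed: %s", stage,
                           conditionMessage(e)),
                   "alltriage_stage_error")
  })
}

# write files to a staging directory, then move into place in one pass so a
# failed run never leaves a partial output bundle
commit_outputs <- function(staging, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(out_dir, f), overwrite = TRUE)
  }
  unlink(staging, recursive = TRUE)
  invisible(out_dir)
}

#' Run the full triage pipeline from a single configuration
#'
#' Orchestrates: VCF ingestion and merging, the three-stage filter cascade,
#' tier/level/pathway classification, the carrier matrix with optional
#' position groups, stratified carrier frequencies, and the level-grouped
#' report — then writes the output bundle plus a machine-readable manifest.
#' Reruns on identical inputs are byte-identical.
#'
#' @param config a list or a YAML file path with fields: `cohort_vcfs`
#'   (character vector/list), `control_vcfs` (optional), `metadata` (TSV:
#'   sample, status, subtype, ethnicity), `catalogs` (named paths:
#'   `population_af`, `mutation_census`, `clinical_levels`, `pathways`,
#'   optionally `common_sites`), `filter` (optional: `population`,
#'   `threshold`, `match_mode`, `coding_consequences`), `stratify`
#'   (metadata attribute, default `"status"`), `groups` (optional
#'   `"GENE:POS"` strings for position aggregation), `out_dir`.
#' @return An object of class `triage_run`: `variants` (surviving
#'   [variant_set()]), `calls` ([classify_variants()] table), `matrix`
#'   ([build_matrix()] result), `frequencies`, `level_report`, `trace`,
#'   `manifest`, `out_dir`.
#' @details Configuration problems raise an `alltriage_config_error`
#'   before anything is written; failures inside a stage raise an
#'   `alltriage_stage_error` naming the stage.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  cohort <- run_stage("read_cohort", {
    merge_variant_sets(lapply(unlist(config$cohort_vcfs), read_vcf))
  })
  controls <- run_stage("read_controls", {
    if (length(config$control_vcfs)) {
      merge_variant_sets(lapply(unlist(config$control_vcfs), read_vcf))
    } else {
      empty_variant_set()
    }
  })
  catalogs <- run_stage("read_catalogs", {
    lapply(setNames(nm = names(config$catalogs)), function(k) {
      read_catalog(config$catalogs[[k]], k)
    })
  })
  metadata <- run_stage("read_metadata", read_tsv(config$metadata))

  fc <- config$filter
  fconf <- filter_config(
    coding_consequences = unlist(fc$coding_consequences) %||%
      DEFAULT_CODING_CONSEQUENCES,
    af_population = fc$population %||% "LAT",
    af_threshold = fc$threshold %||% 0.05,
    match_mode = fc$match_mode %||% "allele")

  cascade <- run_stage("filter_cascade", {
    run_cascade(cohort, controls, catalogs$population_af, fconf)
  })
  calls <- run_stage("classify", {
    classify_variants(cascade$variants, catalogs$mutation_census,
                      catalogs$clinical_levels, catalogs$pathways)
  })
  cm <- run_stage("carrier_matrix", {
    m <- build_matrix(cascade$variants, metadata)
    for (g in config$groups) {
      parts <- strsplit(g, ":", fixed = TRUE)[[1]]
      pos <- suppressWarnings(as.integer(parts[2]))
      m <- tryCatch(aggregate_position(m, parts[1], pos),
                    alltriage_validation_error = function(e) {
                      warning(sprintf("position group '%s' skipped: %s",
                                      g, conditionMessage(e)), call. = FALSE)
                      m
                    })
    }
    m
  })
  freqs <- run_stage("frequencies", {
    do.call(rbind, lapply(colnames(cm$carriers), function(k) {
      rbind(carrier_frequency(cm, k, NULL),
            carrier_frequency(cm, k, config$stratify))
    })) %||% data.frame(key = character(0), stratum = character(0),
                        n_carriers = integer(0), n_total = integer(0),
                        percent = numeric(0))
  })
  level_report <- run_stage("level_report", render_level_report(calls, cm))
  classified_long <- run_stage("variant_table", {
    long_variant_table(calls, cm)
  })

  manifest <- list(
    config_hash = fnv1a_hash(jsonlite::toJSON(
      config[setdiff(names(config), "out_dir")], auto_unbox = TRUE)),
    catalog_hashes = lapply(config$catalogs, function(p) {
      fnv1a_hash(rawToChar(readBin(p, "raw", file.info(p)$size)))
    }),
    n_samples = nrow(cm$meta),
    stages = lapply(seq_len(nrow(cascade$trace)), function(i) {
      as.list(cascade$trace[i, ])
    }),
    n_classified = nrow(calls),
    n_variant_keys = ncol(cm$carriers))

  staging <- tempfile("triage_out_")
  dir.create(staging)
  write_variant_table(classified_long, file.path(staging, "variant_table.tsv"))
  write_tsv(as.data.frame(calls), file.path(staging, "tier_calls.tsv"))
  write_tsv(freqs, file.path(staging, "frequencies.tsv"))
  write_tsv(level_report, file.path(staging, "level_report.tsv"))
  carrier_df <- data.frame(sample = rownames(cm$carriers),
                           cm$carriers, check.names = FALSE,
                           stringsAsFactors = FALSE)
  write_tsv(carrier_df, file.path(staging, "carrier_matrix.tsv"))
  jsonlite::write_json(lapply(seq_len(nrow(cascade$trace)), function(i) {
    as.list(cascade$trace[i, ])
  }), file.path(staging, "trace.json"), auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  commit_outputs(staging, config$out_dir)

  structure(list(variants = cascade$variants, calls = calls, matrix = cm,
                 frequencies = freqs, level_report = level_report,
                 trace = cascade$trace, manifest = manifest,
                 out_dir = config$out_dir),
            class = "triage_run")
}

#' @export
print.triage_run <- function(x, ...) {
  cat("<triage_run>\n")
  print(x$trace)
  cat(sprintf("  %d classified variant(s), %d carrier key(s)\n",
              nrow(x$calls), ncol(x$matrix$carriers)))
  cat(sprintf("  outputs: %s\n", x$out_dir))
  invisible(x)
}

#' @export
summary.triage_run <- function(object, ...) {
  cat("Triage run summary\n")
  cat("==================\n")
  print(object$trace)
  cat("\nTier calls by level:\n")
  print(table(level = ifelse(is.na(object$calls$level), "unleveled",
                             object$calls$level),
              tier = object$calls$tier))
  cat("\nCarrier frequencies (top rows):\n")
  print(utils::head(object$frequencies, 12))
  invisible(object)
}

# per-(patient, variant) long table: one row per carried classified variant
long_variant_table <- function(calls, cm) {
  rows <- list()
  status <- cm$meta$status[match(rownames(cm$carriers), cm$meta$sample)]
  for (i in seq_len(nrow(calls))) {
    key <- paste(calls$gene[i], calls$protein_change[i])
    if (!key %in% colnames(cm$carriers)) next
    carriers <- rownames(cm$carriers)[cm$carriers[, key]]
    if (!length(carriers)) next
    rows[[length(rows) + 1]] <- data.frame(
      sample = carriers,
      gene = calls$gene[i],
      protein_change = calls$protein_change[i],
      aa_pos = calls$aa_pos[i],
      tier = calls$tier[i],
      level = calls$level[i],
      pathway = calls$pathway[i],
      status = status[match(carriers, rownames(cm$carriers))],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample = character(0), gene = character(0),
                      protein_change = character(0), aa_pos = integer(0),
                      tier = character(0), level = integer(0),
                      pathway = character(0), status = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Level-grouped variant report
#'
#' Groups classified variants by clinical-evidence level, then gene, with
#' per-variant carrier counts split by disease status (new-onset versus
#' relapse) — the tabular analogue of a per-level variant figure. Variants
#' whose gene has no catalogued level fall into an `"unleveled"` residual
#' group, so every classified variant appears in exactly one group.
#'
#' @param calls a [classify_variants()] table.
#' @param cm the matching [build_matrix()] result.
#' @return data.frame with columns `level` (`"1"`–`"4"` or `"unleveled"`),
#'   `gene`, `protein_change`, `tier`, `pathway`, `n_newonset`,
#'   `n_relapse`, in deterministic (level, gene, position) order.
#' @export
render_level_report <- function(calls, cm) {
  status <- cm$meta$status[match(rownames(cm$carriers), cm$meta$sample)]
  n <- nrow(calls)
  n_new <- integer(n); n_rel <- integer(n)
  for (i in seq_len(n)) {
    key <- paste(calls$gene[i], calls$protein_change[i])
    if (key %in% colnames(cm$carriers)) {
      col <- cm$carriers[, key]
      n_new[i] <- sum(col & status == "new-onset")
      n_rel[i] <- sum(col & status == "relapse")
    }
  }
  out <- data.frame(
    level = ifelse(is.na(calls$level), "unleveled",
                   as.character(calls$level)),
    gene = calls$gene,
    protein_change = calls$protein_change,
    tier = calls$tier,
    pathway = calls$pathway,
    n_newonset = n_new,
    n_relapse = n_rel,
    stringsAsFactors = FALSE)
  lv_rank <- ifelse(out$level == "unleveled", 99L, as.integer(out$level))
  ord <- order(lv_rank, out$gene, calls$aa_pos, out$protein_change,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an external comparison-cohort carrier-count export
#'
#' The external comparison cohort (a consortium pediatric ALL dataset under
#' dbGaP controlled access) cannot ship with the package; its per-variant
#' carrier counts must be exported by an approved user into a tab-delimited
#' table with columns `variant`, `stratum`, `n_carriers`, `n_total`. This
#' reader is the accession-gated entry point: when the export is absent it
#' raises a classed `alltriage_accession_error` instead of fabricating
#' frequencies.
#'
#' @param path path to the export table.
#' @return data.frame with the four columns above plus `percent`.
#' @seealso [compare_strata()] for the two-stratum fold comparison.
#' @export
read_target_counts <- function(path) {
  if (!file.exists(path)) {
    stop_alltriage(paste0(
      "external-cohort export not found: ", path,
      " (controlled-access data; obtain dbGaP authorisation and export ",
      "carrier counts as variant/stratum/n_carriers/n_total)"),
      "alltriage_accession_error")
  }
  tab <- read_tsv(path)
  required <- c("variant", "stratum", "n_carriers", "n_total")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop_alltriage(paste0("export missing columns: ",
                          paste(missing_cols, collapse = ", ")),
                   "alltriage_load_error")
  }
  tab$percent <- 100 * tab$n_carriers / tab$n_total
  tab
}

#' Two-stratum comparison for one variant of an external-cohort export
#'
#' @param counts result of [read_target_counts()].
#' @param variant variant label to compare (must have exactly two strata).
#' @return A [compare_strata()] result.
#' @export
compare_target_variant <- function(counts, variant) {
  rows <- counts[counts$variant == variant, , drop = FALSE]
  if (nrow(rows) != 2) {
    stop_alltriage(sprintf(
      "variant '%s' must have exactly two strata in the export", variant),
      "alltriage_validation_error")
  }
  freq <- data.frame(key = rows$variant, stratum = rows$stratum,
                     n_carriers = rows$n_carriers, n_total = rows$n_total,
                     percent = rows$percent, stringsAsFactors = FALSE)
  compare_strata(freq)
}
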