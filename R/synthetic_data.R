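# synthetic_data: deterministic generators for cohort/control VCFs,
# catalogue snapshots and reference genotype panels, plus the packaged
# borderland fixture encoding the published patient-variant assignments

# deterministic pseudo-coordinates for a planted protein change: one
# pseudo-contig per gene; position encodes (codon, alternate residue) so
# distinct changes at one codon get distinct allele keys
aa_index <- function(aa) {
  idx <- match(aa, c(AA_CODES, "*", "fs"))
  if (anyNA(idx)) {
    stop_alltriage(sprintf("no synthetic coordinate for residue '%s'",
                           paste(aa[is.na(idx)], collapse = ",")),
                   "alltriage_validation_error")
  }
  idx
}

plant_coordinates <- function(gene, aa_pos, aa_alt) {
  idx <- aa_index(aa_alt)
  data.frame(chrom = paste0("syn_", gene),
             pos = as.integer(aa_pos * 100L + idx),
             ref = "A",
             alt = c("C", "G", "T")[(idx - 1L) %% 3L + 1L],
             stringsAsFactors = FALSE)
}

# assemble a variant_set from a planted table: columns sample, gene,
# protein_change, consequence (+ optional chrom/pos/ref/alt overrides)
planted_variant_set <- function(planted, sample_ids) {
  if (!nrow(planted)) {
    empty <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        gene = character(0), consequence = character(0),
                        protein_change = character(0),
                        aa_ref = character(0), aa_pos = integer(0),
                        aa_alt = character(0), stringsAsFactors = FALSE)
    return(variant_set(empty, matrix(integer(0), 0, length(sample_ids),
                                     dimnames = list(NULL, sample_ids))))
  }
  parsed <- parse_protein_changes(planted$protein_change, warn = FALSE)
  has_coord <- all(c("chrom", "pos", "ref", "alt") %in% names(planted)) &&
    !anyNA(planted$chrom)
  coords <- if (has_coord) {
    planted[c("chrom", "pos", "ref", "alt")]
  } else {
    if (anyNA(parsed$aa_pos)) {
      stop_alltriage(
        "planted variants without explicit coordinates need a parseable protein change",
        "alltriage_validation_error")
    }
    plant_coordinates(planted$gene, parsed$aa_pos, parsed$aa_alt)
  }
  variants <- cbind(coords,
                    data.frame(gene = planted$gene,
                               consequence = planted$consequence,
                               protein_change = planted$protein_change,
                               stringsAsFactors = FALSE),
                    parsed)
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  ukey <- unique(key)
  geno <- matrix(0L, nrow = length(ukey), ncol = length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (r in seq_len(nrow(variants))) {
    geno[match(key[r], ukey), planted$sample[r]] <- 1L
  }
  variant_set(variants[!duplicated(key), , drop = FALSE], geno)
}

#' Specification for a synthetic cohort
#'
#' @param n_patients,n_controls cohort sizes. Defaults mirror the study
#'   design the generator emulates: 9 patients and 7 healthy controls.
#' @param planted data.frame with columns `sample`, `gene`,
#'   `protein_change`, `consequence` — clinically relevant variants planted
#'   with dosage 1 in their named sample only.
#' @param n_background number of random background variants, each carried
#'   by one random patient.
#' @param control_share_prob probability that a background variant is also
#'   carried by a control (removed by control subtraction).
#' @param common_af_prob probability that a background variant is common
#'   (catalogue frequency above the 5 percent threshold; removed by the
#'   population filter).
#' @param seed mandatory integer seed; generation is deterministic.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 9, n_controls = 7,
                        planted = NULL, n_background = 100,
                        control_share_prob = 0.3, common_af_prob = 0.3,
                        seed) {
  if (missing(seed)) {
    stop_alltriage("cohort_spec requires an explicit seed",
                   "alltriage_validation_error")
  }
  if (is.null(planted)) {
    planted <- data.frame(sample = character(0), gene = character(0),
                          protein_change = character(0),
                          consequence = character(0), stringsAsFactors = FALSE)
  }
  probs <- c(control_share_prob, common_af_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_alltriage("probabilities must lie in [0, 1]",
                   "alltriage_validation_error")
  }
  patients <- paste0("P", seq_len(n_patients))
  if (nrow(planted) && !all(planted$sample %in% patients)) {
    stop_alltriage("planted sample ids must be among the patients",
                   "alltriage_validation_error")
  }
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 planted = planted, n_background = n_background,
                 control_share_prob = control_share_prob,
                 common_af_prob = common_af_prob, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with a cascade truth table
#'
#' Generates patient and control variant sets plus a population
#' allele-frequency catalogue and a truth table saying which variants must
#' survive the filter cascade. Planted variants appear with dosage 1 in
#' their named sample only, are never shared with controls and never
#' common, so they survive whenever their consequence is coding.
#' Background variants are random missense changes carried by one random
#' patient each; with the spec'd probabilities they are shared with a
#' random control and/or given a catalogue frequency above the threshold,
#' and survive exactly when neither flag is set. Output is deterministic
#' under the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory; when given, per-sample patient and
#'   control VCFs plus the catalogue and truth table are written there.
#' @return A list of class `synthetic_cohort`: `cohort` and `controls`
#'   ([variant_set()]s), `af_catalog` (population_af table), `truth`
#'   (data.frame with allele keys, flags and `survives`), and `paths` when
#'   `out_dir` was given.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  patients <- paste0("P", seq_len(spec$n_patients))
  controls <- paste0("C", seq_len(spec$n_controls))
  with_seed(spec$seed, {
    n_bg <- spec$n_background
    bg <- NULL
    af_rows <- list()
    ctrl_rows <- NULL
    if (n_bg > 0) {
      aa_ref <- sample(AA_CODES, n_bg, replace = TRUE)
      aa_alt <- vapply(aa_ref, function(r) sample(setdiff(AA_CODES, r), 1), "")
      bg <- data.frame(
        sample = sample(patients, n_bg, replace = TRUE),
        gene = sprintf("BG%04d", seq_len(n_bg)),
        protein_change = paste0(aa_ref, seq_len(n_bg) + 10L, aa_alt),
        consequence = "missense_variant",
        shared = as.logical(rbinom(n_bg, 1, spec$control_share_prob)),
        common = as.logical(rbinom(n_bg, 1, spec$common_af_prob)),
        stringsAsFactors = FALSE)
      parsed <- parse_protein_changes(bg$protein_change, warn = FALSE)
      coords <- plant_coordinates(bg$gene, parsed$aa_pos, parsed$aa_alt)
      bg <- cbind(bg, coords)
      # catalogue rows: common variants get an AF strictly above the 5%
      # threshold; about half the rare ones get a sub-threshold entry, the
      # rest stay out of the catalogue (absence = rarity)
      has_rare_entry <- !bg$common & rbinom(n_bg, 1, 0.5) == 1
      af <- ifelse(bg$common, 0.05 + runif(n_bg) * 0.45, runif(n_bg) * 0.05)
      sel <- bg$common | has_rare_entry
      af_rows <- data.frame(gene = bg$gene[sel], chrom = bg$chrom[sel],
                            pos = bg$pos[sel], ref = bg$ref[sel],
                            alt = bg$alt[sel], population = "LAT",
                            af = af[sel], stringsAsFactors = FALSE)
      if (any(bg$shared)) {
        ctrl_rows <- bg[bg$shared, , drop = FALSE]
        ctrl_rows$sample <- sample(controls, nrow(ctrl_rows), replace = TRUE)
      }
    } else {
      af_rows <- data.frame(gene = character(0), chrom = character(0),
                            pos = integer(0), ref = character(0),
                            alt = character(0), population = character(0),
                            af = numeric(0), stringsAsFactors = FALSE)
    }
    planted_all <- spec$planted
    cohort_tab <- rbind(
      if (nrow(planted_all)) planted_all[c("sample", "gene", "protein_change",
                                           "consequence")],
      if (!is.null(bg)) bg[c("sample", "gene", "protein_change",
                             "consequence")])
    if (is.null(cohort_tab)) {
      cohort_tab <- data.frame(sample = character(0), gene = character(0),
                               protein_change = character(0),
                               consequence = character(0),
                               stringsAsFactors = FALSE)
    }
    cohort <- planted_variant_set(cohort_tab, patients)
    ctrl_tab <- if (!is.null(ctrl_rows)) {
      ctrl_rows[c("sample", "gene", "protein_change", "consequence")]
    } else {
      data.frame(sample = character(0), gene = character(0),
                 protein_change = character(0), consequence = character(0),
                 stringsAsFactors = FALSE)
    }
    control_vs <- planted_variant_set(ctrl_tab, controls)

    truth_planted <- if (nrow(planted_all)) {
      parsed_p <- parse_protein_changes(planted_all$protein_change,
                                        warn = FALSE)
      coords_p <- plant_coordinates(planted_all$gene, parsed_p$aa_pos,
                                    parsed_p$aa_alt)
      data.frame(coords_p,
                 gene = planted_all$gene,
                 protein_change = planted_all$protein_change,
                 sample = planted_all$sample,
                 planted = TRUE, shared_with_control = FALSE,
                 common_af = FALSE,
                 survives = planted_all$consequence %in%
                   DEFAULT_CODING_CONSEQUENCES,
                 stringsAsFactors = FALSE)
    }
    truth_bg <- if (!is.null(bg)) {
      data.frame(bg[c("chrom", "pos", "ref", "alt", "gene",
                      "protein_change", "sample")],
                 planted = FALSE, shared_with_control = bg$shared,
                 common_af = bg$common,
                 survives = !bg$shared & !bg$common,
                 stringsAsFactors = FALSE)
    }
    truth <- rbind(truth_planted, truth_bg)
    if (is.null(truth)) {
      truth <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          gene = character(0), protein_change = character(0),
                          sample = character(0), planted = logical(0),
                          shared_with_control = logical(0),
                          common_af = logical(0), survives = logical(0),
                          stringsAsFactors = FALSE)
    }
    out <- structure(list(cohort = cohort, controls = control_vs,
                          af_catalog = af_rows, truth = truth),
                     class = "synthetic_cohort")
    if (!is.null(out_dir)) {
      out$paths <- write_synthetic_cohort(out, out_dir, patients, controls)
    }
    out
  })
}

# write per-sample VCFs plus catalogue and truth table
write_synthetic_cohort <- function(x, out_dir, patients, controls) {
  dir.create(file.path(out_dir, "patients"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "controls"), recursive = TRUE,
             showWarnings = FALSE)
  single_sample <- function(vs, sm) {
    carried <- !is.na(vs$geno[, sm]) & vs$geno[, sm] >= 1
    vs_subset(variant_set(vs$variants,
                          vs$geno[, sm, drop = FALSE]), carried)
  }
  patient_vcfs <- vapply(patients, function(p) {
    path <- file.path(out_dir, "patients", paste0(p, ".vcf"))
    write_vcf(single_sample(x$cohort, p), path)
    path
  }, "")
  control_vcfs <- vapply(controls, function(cn) {
    path <- file.path(out_dir, "controls", paste0(cn, ".vcf"))
    write_vcf(single_sample(x$controls, cn), path)
    path
  }, "")
  af_path <- file.path(out_dir, "population_af.tsv")
  write_tsv(x$af_catalog, af_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  write_tsv(x$truth, truth_path)
  list(patient_vcfs = patient_vcfs, control_vcfs = control_vcfs,
       af_catalog = af_path, truth = truth_path)
}

#' Specification for a synthetic reference genotype panel
#'
#' @param populations list of population descriptors, each a list with
#'   `label`, `n_samples`, and `af` (allele-frequency vector of length
#'   `n_loci`, values in \[0, 1\]).
#' @param n_loci number of biallelic loci.
#' @param seed mandatory integer seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(populations, n_loci, seed) {
  if (missing(seed)) {
    stop_alltriage("panel_spec requires an explicit seed",
                   "alltriage_validation_error")
  }
  if (n_loci < 1) {
    stop_alltriage("n_loci must be >= 1", "alltriage_validation_error")
  }
  for (p in populations) {
    if (length(p$af) != n_loci || any(p$af < 0 | p$af > 1)) {
      stop_alltriage(sprintf(
        "population '%s': af must have length n_loci with values in [0, 1]",
        p$label %||% "?"), "alltriage_validation_error")
    }
  }
  structure(list(populations = populations, n_loci = as.integer(n_loci),
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Generate a synthetic reference genotype panel
#'
#' Draws dosages binomially (2 trials) from each population's
#' allele-frequency vector under Hardy-Weinberg, deterministically for a
#' given seed. Loci are placed on a single pseudo-contig. No linkage
#' disequilibrium is simulated.
#'
#' @param spec a [panel_spec()].
#' @return A [genotype_panel()] with every sample labelled by its
#'   generating population.
#' @export
generate_reference_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    loci <- data.frame(chrom = "syn_panel",
                       pos = seq_len(spec$n_loci) * 10L,
                       ref = "A", alt = "G", stringsAsFactors = FALSE)
    mats <- list(); labels <- character(0); ids <- character(0)
    for (p in spec$populations) {
      # column-major fill: each column is one locus drawn at that locus's af
      m <- matrix(rbinom(p$n_samples * spec$n_loci, 2,
                         rep(p$af, each = p$n_samples)),
                  nrow = p$n_samples, ncol = spec$n_loci)
      mats[[length(mats) + 1]] <- m
      labels <- c(labels, rep(p$label, p$n_samples))
      ids <- c(ids, paste0(p$label, "_", seq_len(p$n_samples)))
    }
    dos <- do.call(rbind, mats)
    rownames(dos) <- ids
    genotype_panel(dos, loci, labels)
  })
}

#' Simulate a two-population ancestry benchmark
#'
#' Builds a labelled reference panel from two populations whose allele
#' frequencies differ by a fixed gap at every locus, plus unlabelled query
#' samples drawn alternately from the two populations with the truth
#' recorded — the standard setting for checking that the first MDS
#' dimension separates divergent populations.
#'
#' @param n_loci number of loci (default 500).
#' @param gap allele-frequency gap between the populations (default 0.5).
#' @param n_ref reference samples per population (default 50).
#' @param n_query number of unlabelled query samples (default 20).
#' @param seed integer seed.
#' @return A list: `panel` (reference + query [genotype_panel()], queries
#'   unlabelled) and `truth` (data.frame `sample`, `population`).
#' @export
simulate_ancestry_cohort <- function(n_loci = 500, gap = 0.5, n_ref = 50,
                                     n_query = 20, seed) {
  if (missing(seed)) {
    stop_alltriage("simulate_ancestry_cohort requires a seed",
                   "alltriage_validation_error")
  }
  with_seed(seed, {
    af_a <- runif(n_loci, 0.05, 0.95 - gap)
    af_b <- af_a + gap
    ref <- generate_reference_panel(panel_spec(
      populations = list(list(label = "POPA", n_samples = n_ref, af = af_a),
                         list(label = "POPB", n_samples = n_ref, af = af_b)),
      n_loci = n_loci, seed = sample.int(2^30, 1)))
    truth_pop <- rep(c("POPA", "POPB"), length.out = n_query)
    qdos <- matrix(0L, nrow = n_query, ncol = n_loci,
                   dimnames = list(paste0("Q", seq_len(n_query)), NULL))
    for (i in seq_len(n_query)) {
      qdos[i, ] <- rbinom(n_loci, 2, if (truth_pop[i] == "POPA") af_a else af_b)
    }
    dos <- rbind(ref$dosages, qdos)
    panel <- genotype_panel(dos, ref$loci,
                            c(ref$populations, rep(NA_character_, n_query)))
    list(panel = panel,
         truth = data.frame(sample = rownames(qdos), population = truth_pop,
                            stringsAsFactors = FALSE))
  })
}

# ---------------------------------------------------------------------------
# the borderland fixture: the published patient-variant assignments with a
# synthetic catalogue bundle reconstructing the printed tiers and levels

borderland_planted <- function() {
  tab <- rbind(
    c("P1", "ATM",    "E2366*", "stop_gained"),
    c("P1", "DNMT3A", "A999G",  "missense_variant"),
    c("P1", "TET2",   "A999G",  "missense_variant"),
    c("P1", "STAT5B", "N642H",  "missense_variant"),
    c("P1", "NOTCH2", "N7S",    "missense_variant"),
    c("P1", "NOTCH2", "E38K",   "missense_variant"),
    c("P2", "SUZ12",  "A999G",  "missense_variant"),
    c("P2", "NOTCH2", "C19W",   "missense_variant"),
    c("P3", "WT1",    "C303*",  "stop_gained"),
    c("P4", "NOTCH2", "C19W",   "missense_variant"),
    c("P5", "SOCS1",  "L174D",  "missense_variant"),
    c("P7", "ROS1",   "S1109L", "missense_variant"),
    c("P7", "PTEN",   "A999G",  "missense_variant"),
    c("P7", "NOTCH2", "C19W",   "missense_variant"),
    c("P8", "KRAS",   "G12A",   "missense_variant"),
    c("P8", "NOTCH2", "C19W",   "missense_variant"),
    c("P9", "NOTCH2", "C19W",   "missense_variant"),
    # decoys exercising the three cascade stages
    c("P3", "DECOYNC",     "A10T", "intron_variant"),
    c("P2", "DECOYCTRL",   "A10T", "missense_variant"),
    c("P5", "DECOYCOMMON", "A20T", "missense_variant"))
  data.frame(sample = tab[, 1], gene = tab[, 2], protein_change = tab[, 3],
             consequence = tab[, 4], stringsAsFactors = FALSE)
}

borderland_metadata <- function() {
  data.frame(
    sample = paste0("P", 1:9),
    status = c("relapse", "relapse", "new-onset", "new-onset", "relapse",
               "relapse", "relapse", "new-onset", "new-onset"),
    subtype = c("T-ALL", "pre-T-ALL", "pre-T-ALL", "pre-T-ALL",
                "early pre-B-ALL", "early pre-B-ALL", "pre-T-ALL",
                "early pre-B-ALL", "early pre-B-ALL"),
    ethnicity = rep("Hispanic", 9),
    stringsAsFactors = FALSE)
}

borderland_census <- function() {
  tab <- rbind(
    # gene, aa_ref, aa_pos, aa_alt, f1, f2, f3, label
    c("KRAS",   "G", 12,   "A", 1, 1, 0, "tier1"),
    c("KRAS",   "G", 12,   "D", 1, 1, 1, "tier1"),
    c("KRAS",   "A", 59,   "E", 0, 0, 0, "other"),
    c("ROS1",   "S", 1109, "L", 0, 0, 1, "tier3"),
    c("ATM",    "E", 2366, "K", 0, 1, 0, "tier3"),
    c("WT1",    "C", 303,  "*", 0, 1, 0, "tier3"),
    c("STAT5B", "N", 642,  "H", 0, 0, 1, "tier3"),
    c("NOTCH2", "C", 19,   "W", 0, 1, 0, "tier3"),
    c("NOTCH2", "E", 38,   "K", 0, 0, 1, "tier3"),
    c("NOTCH2", "N", 7,    "K", 0, 0, 1, "tier3"),
    c("SOCS1",  "L", 174,  "P", 0, 0, 1, "tier3"),
    c("DNMT3A", "A", 999,  "V", 0, 0, 1, "tier3"),
    c("TET2",   "A", 999,  "V", 0, 0, 1, "tier3"),
    c("SUZ12",  "A", 999,  "V", 0, 0, 1, "tier3"),
    c("PTEN",   "A", 999,  "V", 0, 0, 1, "tier3"))
  data.frame(gene = tab[, 1], aa_ref = tab[, 2],
             aa_pos = as.integer(tab[, 3]), aa_alt = tab[, 4],
             f_recurrent_driver = as.integer(tab[, 5]),
             f_clinvar_pathogenic = as.integer(tab[, 6]),
             f_dnds_selection = as.integer(tab[, 7]),
             cmc_label = tab[, 8], stringsAsFactors = FALSE)
}

borderland_levels <- function() {
  tab <- rbind(
    c("ROS1",   "therapeutic", 1),
    c("ATM",    "therapeutic", 1),
    c("KRAS",   "therapeutic", 1),
    c("DNMT3A", "diagnostic",  2),
    c("DNMT3A", "prognostic",  2),
    c("TET2",   "diagnostic",  2),
    c("WT1",    "diagnostic",  2),
    c("STAT5B", "diagnostic",  3),
    c("SUZ12",  "diagnostic",  3),
    c("PTEN",   "diagnostic",  3),
    c("NOTCH2", "diagnostic",  3),
    c("SOCS1",  "diagnostic",  3))
  data.frame(gene = tab[, 1], category = tab[, 2],
             level = as.integer(tab[, 3]), stringsAsFactors = FALSE)
}

borderland_pathways <- function() {
  tab <- rbind(
    c("KRAS",   "MAPK"),
    c("ROS1",   "RTK"),
    c("ATM",    "DNA damage response"),
    c("STAT5B", "JAK/STAT"),
    c("SOCS1",  "JAK/STAT"),
    c("DNMT3A", "epigenetic/chromatin remodeling"),
    c("TET2",   "epigenetic/chromatin remodeling"),
    c("WT1",    "epigenetic/chromatin remodeling"),
    c("SUZ12",  "epigenetic/chromatin remodeling"),
    c("PTEN",   "PI3K"),
    c("NOTCH2", "NOTCH"))
  data.frame(gene = tab[, 1], pathway = tab[, 2], stringsAsFactors = FALSE)
}

borderland_af <- function() {
  # ROS1 S1109L carries its published Latino/Admixed American frequency
  # (0.016% = 0.00016); the common decoy sits well above the 5% threshold
  ros1 <- plant_coordinates("ROS1", 1109, "L")
  kras <- plant_coordinates("KRAS", 12, "A")
  decoy <- plant_coordinates("DECOYCOMMON", 20, "T")
  data.frame(
    gene = c("ROS1", "KRAS", "DECOYCOMMON"),
    chrom = c(ros1$chrom, kras$chrom, decoy$chrom),
    pos = c(ros1$pos, kras$pos, decoy$pos),
    ref = c(ros1$ref, kras$ref, decoy$ref),
    alt = c(ros1$alt, kras$alt, decoy$alt),
    population = "LAT",
    af = c(0.00016, 0.0005, 0.12),
    stringsAsFactors = FALSE)
}

borderland_common_sites <- function() {
  data.frame(chrom = "syn_panel", pos = seq_len(20) * 10L,
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

#' The borderland fixture: published patient-variant assignments
#'
#' Builds the packaged fixture encoding a nine-patient ALL cohort with the
#' published variant assignments (e.g. NOTCH2 C19W in patients 2, 4, 7, 8
#' and 9; KRAS G12A in patient 8; STAT5B N642H in patient 1; patient 6
#' carries no surviving variant), Table-1-style metadata (four new-onset,
#' five relapse, all Hispanic), and a synthetic catalogue bundle
#' reconstructing the printed tiers, clinical levels and pathways. Exact
#' amino-acid changes for the DNMT3A, TET2, SUZ12 and PTEN variants are not
#' public; they are encoded as clearly synthetic placeholders (`A999G`
#' against a census sibling `A999V`) that classify Tier X. Three decoy
#' variants exercise the cascade: a non-coding change, a control-shared
#' change, and a common (12 percent) polymorphism.
#'
#' The fixture path is fully deterministic (no randomness).
#'
#' @param dir optional directory; when given, per-patient and per-control
#'   VCFs, `metadata.tsv`, the catalogue bundle (files prefixed
#'   `synthetic_`), a `config.yaml` consumable by [run_pipeline()], and a
#'   `MANIFEST.txt` flagging the reconstructions are written there.
#' @return A list of class `borderland_fixture`: `cohort`, `controls`
#'   ([variant_set()]s), `metadata`, `catalogs` (list: `population_af`,
#'   `mutation_census`, `clinical_levels`, `pathways`, `common_sites`),
#'   and `paths`/`config` when `dir` was given.
#' @export
borderland_fixture <- function(dir = NULL) {
  planted <- borderland_planted()
  patients <- paste0("P", 1:9)
  ctrl_ids <- paste0("C", 1:7)
  cohort <- planted_variant_set(planted, patients)
  # control C1 carries the control-shared decoy; C2 a private benign variant
  ctrl_tab <- data.frame(
    sample = c("C1", "C2"),
    gene = c("DECOYCTRL", "CTRLPRIV"),
    protein_change = c("A10T", "A30T"),
    consequence = c("missense_variant", "missense_variant"),
    stringsAsFactors = FALSE)
  controls <- planted_variant_set(ctrl_tab, ctrl_ids)
  catalogs <- list(population_af = borderland_af(),
                   mutation_census = borderland_census(),
                   clinical_levels = borderland_levels(),
                   pathways = borderland_pathways(),
                   common_sites = borderland_common_sites())
  out <- structure(list(cohort = cohort, controls = controls,
                        metadata = borderland_metadata(),
                        catalogs = catalogs),
                   class = "borderland_fixture")
  if (!is.null(dir)) {
    dir.create(file.path(dir, "patients"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "controls"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "catalogs"), recursive = TRUE,
               showWarnings = FALSE)
    single_sample <- function(vs, sm) {
      carried <- !is.na(vs$geno[, sm]) & vs$geno[, sm] >= 1
      vs_subset(variant_set(vs$variants, vs$geno[, sm, drop = FALSE]),
                carried)
    }
    patient_vcfs <- vapply(patients, function(p) {
      path <- file.path(dir, "patients", paste0(p, ".vcf"))
      write_vcf(single_sample(cohort, p), path)
      path
    }, "")
    control_vcfs <- vapply(ctrl_ids, function(cn) {
      path <- file.path(dir, "controls", paste0(cn, ".vcf"))
      write_vcf(single_sample(controls, cn), path)
      path
    }, "")
    meta_path <- file.path(dir, "metadata.tsv")
    write_tsv(out$metadata, meta_path)
    cat_paths <- list()
    for (kind in names(catalogs)) {
      p <- file.path(dir, "catalogs", paste0("synthetic_", kind, ".tsv"))
      write_tsv(catalogs[[kind]], p)
      cat_paths[[kind]] <- p
    }
    writeLines(c(
      "Borderland fixture manifest",
      "",
      "Synthetic stand-ins, not real database extracts:",
      "  - catalogs/synthetic_*.tsv reconstruct catalogue content consistent",
      "    with the published tier/level assignments; the factor combinations",
      "    behind each tier are reconstructions.",
      "  - DNMT3A/TET2/SUZ12/PTEN protein changes are placeholders (A999G)",
      "    because the exact published changes are not in the text; they are",
      "    excluded from exact-change checks.",
      "  - ATM E2366* is reconstructed from the reported similar variant.",
      "  - DECOYNC/DECOYCTRL/DECOYCOMMON/CTRLPRIV are cascade decoys.",
      "  - Genomic coordinates are synthetic (one pseudo-contig per gene)."),
      file.path(dir, "MANIFEST.txt"))
    config <- list(
      cohort_vcfs = as.list(unname(patient_vcfs)),
      control_vcfs = as.list(unname(control_vcfs)),
      metadata = meta_path,
      catalogs = lapply(cat_paths, identity),
      filter = list(population = "LAT", threshold = 0.05,
                    match_mode = "allele"),
      stratify = "status",
      groups = list("KRAS:12"),
      out_dir = file.path(dir, "out"))
    config_path <- file.path(dir, "config.yaml")
    yaml::write_yaml(config, config_path)
    out$paths <- list(patient_vcfs = patient_vcfs,
                      control_vcfs = control_vcfs,
                      metadata = meta_path, catalogs = cat_paths,
                      config = config_path)
    out$config <- config
  }
  out
}
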