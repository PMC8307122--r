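# shared test helpers: tiny VCF text fixtures built in code, and
# brute-force oracles kept independent of the implementation paths

write_test_vcf <- function(body_lines, samples = character(0),
                           path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=A,Type=String,Description=\"gene|consequence|protein_change\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

# quick variant table -> variant_set; rows: list(chrom, pos, ref, alt, gene,
# consequence, protein_change); geno given as a dosage matrix
make_vs <- function(tab, geno = NULL) {
  tab$protein_change[is.na(tab$protein_change)] <- NA_character_
  parsed <- alltriage:::parse_protein_changes(tab$protein_change, warn = FALSE)
  if (is.null(geno)) {
    geno <- matrix(1L, nrow = nrow(tab), ncol = 1,
                   dimnames = list(NULL, "S1"))
  }
  variant_set(cbind(tab, parsed), geno)
}

rand_token <- function() {
  ref <- sample(alltriage:::AA_CODES, 1)
  alt <- sample(setdiff(c(alltriage:::AA_CODES, "*", "fs"), ref), 1)
  paste0(ref, sample.int(2000, 1), alt)
}

# brute-force tier classifier: full census scan per query, written straight
# from the tier definitions, independent of classify_variant_tier internals
brute_force_tier <- function(gene, aa_ref, aa_pos, aa_alt, census) {
  rec_tier <- function(r) {
    if (tolower(r$cmc_label) == "other") return("Other")
    f <- c(r$f_recurrent_driver, r$f_clinvar_pathogenic, r$f_dnds_selection)
    if (f[1] && f[2]) "Tier1"
    else if (sum(f) >= 2) "Tier2"
    else if (sum(f) == 1) "Tier3"
    else "Other"
  }
  exact <- NULL
  pos_tiered <- FALSE
  for (i in seq_len(nrow(census))) {
    r <- census[i, ]
    if (r$gene != gene || r$aa_pos != aa_pos) next
    if (rec_tier(r) %in% c("Tier1", "Tier2", "Tier3")) pos_tiered <- TRUE
    if (!is.na(aa_ref) && r$aa_ref == aa_ref && r$aa_alt == aa_alt &&
        aa_alt != "fs") {
      exact <- r
    }
  }
  if (!is.null(exact)) {
    if (tolower(exact$cmc_label) == "other" && pos_tiered) return("TierX")
    f <- c(exact$f_recurrent_driver, exact$f_clinvar_pathogenic,
           exact$f_dnds_selection)
    if (f[1] && f[2]) return("Tier1")
    if (sum(f) >= 2) return("Tier2")
    if (sum(f) == 1) return("Tier3")
    return("Other")
  }
  if (pos_tiered) return("TierX")
  "Unranked"
}

# random small cohort pair for cascade property tests (in-memory, no I/O)
rand_cascade_inputs <- function(n = 30) {
  conseq_pool <- c("missense_variant", "stop_gained", "intron_variant",
                   "synonymous_variant", "unannotated")
  tab <- data.frame(
    chrom = "chrT",
    pos = sample.int(10000, n),
    ref = "A",
    alt = sample(c("C", "G", "T"), n, replace = TRUE),
    gene = sprintf("G%03d", seq_len(n)),
    consequence = sample(conseq_pool, n, replace = TRUE),
    protein_change = NA_character_,
    stringsAsFactors = FALSE)
  geno <- matrix(sample(0:1, n * 2, replace = TRUE), ncol = 2,
                 dimnames = list(NULL, c("P1", "P2")))
  cohort <- make_vs(tab, geno)
  in_controls <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.3, .7))
  ctrl_tab <- tab[in_controls, , drop = FALSE]
  ctrl_geno <- matrix(1L, nrow = nrow(ctrl_tab), ncol = 1,
                      dimnames = list(NULL, "C1"))
  controls <- make_vs(ctrl_tab, ctrl_geno)
  has_af <- sample(c(TRUE, FALSE), n, replace = TRUE)
  af <- data.frame(gene = tab$gene[has_af], chrom = tab$chrom[has_af],
                   pos = tab$pos[has_af], ref = tab$ref[has_af],
                   alt = tab$alt[has_af], population = "LAT",
                   af = runif(sum(has_af), 0, 0.2), stringsAsFactors = FALSE)
  list(cohort = cohort, controls = controls, af = af)
}
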