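test_that("the factor rules cover all eight combinations exactly", {
  combos <- expand.grid(f1 = c(FALSE, TRUE), f2 = c(FALSE, TRUE),
                        f3 = c(FALSE, TRUE))
  got <- tier_from_factors(combos$f1, combos$f2, combos$f3)
  expected <- character(8)
  for (i in 1:8) {
    f <- unlist(combos[i, ])
    expected[i] <- if (f[1] && f[2]) "Tier1"
      else if (sum(f) == 2) "Tier2"
      else if (sum(f) == 1) "Tier3"
      else "Other"
  }
  expect_equal(got, expected)
  # spot checks straight from the rule definitions
  expect_equal(tier_from_factors(TRUE, TRUE, FALSE), "Tier1")
  expect_equal(tier_from_factors(TRUE, TRUE, TRUE), "Tier1")
  expect_equal(tier_from_factors(TRUE, FALSE, TRUE), "Tier2")
  expect_equal(tier_from_factors(FALSE, TRUE, TRUE), "Tier2")
  expect_equal(tier_from_factors(FALSE, FALSE, TRUE), "Tier3")
  expect_equal(tier_from_factors(FALSE, FALSE, FALSE), "Other")
})

test_that("adding an evidence factor never lowers the tier", {
  severity <- c(Tier1 = 1, Tier2 = 2, Tier3 = 3, Other = 4)
  combos <- expand.grid(f1 = c(FALSE, TRUE), f2 = c(FALSE, TRUE),
                        f3 = c(FALSE, TRUE))
  for (i in 1:8) {
    for (j in 1:3) {
      if (combos[i, j]) next
      upgraded <- combos[i, ]
      upgraded[j] <- TRUE
      t_lo <- tier_from_factors(combos$f1[i], combos$f2[i], combos$f3[i])
      t_hi <- do.call(tier_from_factors, unname(as.list(unlist(upgraded))))
      expect_lte(severity[[t_hi]], severity[[t_lo]])
    }
  }
})

test_that("missing factors are rejected", {
  expect_error(tier_from_factors(NA, TRUE, FALSE),
               class = "alltriage_validation_error")
})

census_fixture <- function() {
  data.frame(
    gene = c("KRAS", "KRAS", "STAT5B", "BRAF", "BRAF"),
    aa_ref = c("G", "G", "N", "V", "V"),
    aa_pos = c(12L, 12L, 642L, 600L, 600L),
    aa_alt = c("A", "D", "H", "E", "K"),
    f_recurrent_driver = c(1L, 1L, 0L, 1L, 0L),
    f_clinvar_pathogenic = c(1L, 1L, 0L, 1L, 0L),
    f_dnds_selection = c(0L, 1L, 1L, 1L, 0L),
    cmc_label = c("tier1", "tier1", "tier3", "tier1", "other"),
    stringsAsFactors = FALSE)
}

test_that("exact census matches classify by their factors", {
  census <- census_fixture()
  tc <- classify_variant_tier("KRAS", "G", 12L, "A", census)
  expect_equal(tc$tier, "Tier1")
  expect_equal(tc$basis, "exact")
  tc2 <- classify_variant_tier("STAT5B", "N", 642L, "H", census)
  expect_equal(tc2$tier, "Tier3")
  expect_equal(tc2$basis, "exact")
})

test_that("uncatalogued changes at tiered positions become Tier X", {
  census <- census_fixture()
  # Q61-style: alt not catalogued at a position holding Tier1 records
  tc <- classify_variant_tier("KRAS", "G", 12L, "V", census)
  expect_equal(tc$tier, "TierX")
  expect_equal(tc$basis, "position")
  # exact match labelled "other" at a position with a Tier1 sibling
  tc2 <- classify_variant_tier("BRAF", "V", 600L, "K", census)
  expect_equal(tc2$tier, "TierX")
  expect_equal(tc2$basis, "exact")
  # frameshift never matches exactly but still inherits position Tier X
  tc3 <- classify_variant_tier("KRAS", "G", 12L, "fs", census)
  expect_equal(tc3$tier, "TierX")
  expect_equal(tc3$basis, "position")
})

test_that("positions without tiered records are Unranked", {
  census <- census_fixture()
  expect_equal(classify_variant_tier("KRAS", "G", 13L, "D", census)$tier,
               "Unranked")
  expect_equal(classify_variant_tier("NOGENE", "A", 5L, "T", census)$tier,
               "Unranked")
  # an exact "other" match with no tiered sibling keeps its factor tier
  lone_other <- census_fixture()[5, , drop = FALSE]
  tc <- classify_variant_tier("BRAF", "V", 600L, "K", lone_other)
  expect_equal(tc$tier, "Other")
  expect_equal(tc$basis, "exact")
})

test_that("reference amino-acid conflicts warn but still position-match", {
  census <- census_fixture()
  expect_warning(
    tc <- classify_variant_tier("KRAS", "R", 12L, "C", census),
    "conflicts")
  expect_equal(tc$tier, "TierX")
  expect_equal(tc$basis, "position")
})

test_that("classification agrees with a brute-force census scan", {
  withr::local_seed(31)
  genes <- c("GA", "GB", "GC")
  for (rep in 1:30) {
    n <- 12
    census <- data.frame(
      gene = sample(genes, n, replace = TRUE),
      aa_ref = sample(alltriage:::AA_CODES[1:4], n, replace = TRUE),
      aa_pos = sample(1:5, n, replace = TRUE),
      aa_alt = sample(c(alltriage:::AA_CODES[5:9], "*"), n, replace = TRUE),
      f_recurrent_driver = sample(0:1, n, replace = TRUE),
      f_clinvar_pathogenic = sample(0:1, n, replace = TRUE),
      f_dnds_selection = sample(0:1, n, replace = TRUE),
      cmc_label = sample(c("tier1", "tier3", "other"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    census <- census[!duplicated(census[c("gene", "aa_ref", "aa_pos",
                                          "aa_alt")]), ]
    for (q in 1:10) {
      gene <- sample(genes, 1)
      pos <- sample(1:5, 1)
      at_pos <- census[census$gene == gene & census$aa_pos == pos, ]
      aa_ref <- if (nrow(at_pos)) at_pos$aa_ref[1]
                else sample(alltriage:::AA_CODES[1:4], 1)
      aa_alt <- sample(c(alltriage:::AA_CODES[5:9], "*", "fs"), 1)
      got <- suppressWarnings(
        classify_variant_tier(gene, aa_ref, pos, aa_alt, census))
      want <- brute_force_tier(gene, aa_ref, pos, aa_alt, census)
      expect_equal(got$tier, want)
      # an exact self-match is never Tier X unless labelled "other"
      if (got$basis == "exact" && got$tier == "TierX") {
        rec <- census[census$gene == gene & census$aa_pos == pos &
                        census$aa_ref == aa_ref & census$aa_alt == aa_alt, ]
        expect_equal(tolower(rec$cmc_label), "other")
      }
    }
  }
})

test_that("clinical level takes the strongest level across categories", {
  levels_tab <- data.frame(
    gene = c("ROS1", "MIXED", "MIXED"),
    category = c("therapeutic", "diagnostic", "prognostic"),
    level = c(1L, 2L, 3L), stringsAsFactors = FALSE)
  expect_equal(assign_clinical_level("ROS1", levels_tab),
               list(level = 1L, categories = "therapeutic"))
  got <- assign_clinical_level("MIXED", levels_tab)
  expect_equal(got$level, 2L)
  expect_equal(got$categories, "diagnostic")
  absent <- assign_clinical_level("NOPE", levels_tab)
  expect_true(is.na(absent$level))
  expect_length(absent$categories, 0)
})

test_that("pathway mapping returns all memberships, empty when unknown", {
  pw <- data.frame(gene = c("STAT5B", "SOCS1", "DNMT3A", "DNMT3A"),
                   pathway = c("JAK/STAT", "JAK/STAT",
                               "epigenetic/chromatin remodeling", "PI3K"),
                   stringsAsFactors = FALSE)
  expect_equal(map_pathway("STAT5B", pw), "JAK/STAT")
  expect_equal(map_pathway("DNMT3A", pw),
               c("PI3K", "epigenetic/chromatin remodeling"))
  expect_length(map_pathway("UNKNOWN", pw), 0)
})

test_that("classify_variants joins tier, level and pathway per variant", {
  d <- withr::local_tempdir()
  f <- borderland_fixture(d)
  cr <- run_cascade(f$cohort, f$controls, f$catalogs$population_af)
  calls <- classify_variants(cr$variants, f$catalogs$mutation_census,
                             f$catalogs$clinical_levels, f$catalogs$pathways)
  pick <- function(g, pc) calls[calls$gene == g & calls$protein_change == pc, ]
  expect_equal(pick("KRAS", "G12A")$tier, "Tier1")
  expect_equal(pick("KRAS", "G12A")$level, 1L)
  expect_equal(pick("ROS1", "S1109L")$tier, "Tier3")
  expect_equal(pick("ATM", "E2366*")$tier, "TierX")
  expect_equal(pick("ATM", "E2366*")$basis, "position")
  expect_equal(pick("STAT5B", "N642H")$tier, "Tier3")
  expect_equal(pick("STAT5B", "N642H")$level, 3L)
  expect_equal(pick("STAT5B", "N642H")$pathway, "JAK/STAT")
  expect_equal(pick("WT1", "C303*")$tier, "Tier3")
  expect_equal(pick("WT1", "C303*")$level, 2L)
})
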