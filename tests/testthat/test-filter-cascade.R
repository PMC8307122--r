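coding_tab <- function() {
  data.frame(
    chrom = "chr1", pos = 1:5 * 10L, ref = "A",
    alt = c("C", "G", "T", "C", "G"),
    gene = paste0("G", 1:5),
    consequence = c("missense_variant", "intron_variant", "stop_gained",
                    "synonymous_variant", "unannotated"),
    protein_change = NA_character_, stringsAsFactors = FALSE)
}

vs_subset_empty <- function(vs) alltriage:::vs_subset(vs, integer(0))

test_that("coding restriction keeps exactly the coding consequences", {
  vs <- make_vs(coding_tab())
  out <- restrict_coding(vs)
  # enumerating the predicate over the toy set: missense + stop_gained
  expect_equal(sort(out$variants$gene), c("G1", "G3"))
  expect_equal(n_variants(restrict_coding(vs_subset_empty(vs))), 0L)
})

test_that("control subtraction removes any allele carried by any control", {
  tab <- coding_tab()
  vs <- make_vs(tab)
  # control het at G1's site in one of 7 controls
  ctrl_geno <- matrix(0L, nrow = 1, ncol = 7,
                      dimnames = list(NULL, paste0("C", 1:7)))
  ctrl_geno[1, 3] <- 1L
  controls <- make_vs(tab[1, , drop = FALSE], ctrl_geno)
  out <- subtract_controls(vs, controls)
  expect_false("G1" %in% out$variants$gene)
  expect_equal(n_variants(out), 4L)

  # a control site with zero carriers removes nothing
  ctrl_geno[1, 3] <- 0L
  controls0 <- make_vs(tab[1, , drop = FALSE], ctrl_geno)
  expect_equal(n_variants(subtract_controls(vs, controls0)), 5L)
})

test_that("control subtraction equals a set-difference oracle on planted overlaps", {
  withr::local_seed(7)
  for (rep in 1:20) {
    n <- 40
    k <- sample.int(n, 1)
    tab <- data.frame(chrom = "chrT", pos = sample.int(5000, n), ref = "A",
                      alt = "G", gene = sprintf("G%02d", 1:n),
                      consequence = "missense_variant",
                      protein_change = NA_character_,
                      stringsAsFactors = FALSE)
    vs <- make_vs(tab)
    shared_idx <- sample.int(n, k)
    controls <- make_vs(tab[shared_idx, , drop = FALSE],
                        matrix(1L, nrow = k, ncol = 1,
                               dimnames = list(NULL, "C1")))
    out <- subtract_controls(vs, controls)
    expect_equal(n_variants(out), n - k)
    expect_setequal(out$variants$gene, tab$gene[-shared_idx])
  }
})

test_that("the population filter removes strictly-greater-than-threshold alleles", {
  afs <- c(0.001, 0.04, 0.05, 0.051, 0.5)
  tab <- data.frame(chrom = "chr2", pos = 1:5 * 7L, ref = "A", alt = "T",
                    gene = paste0("A", 1:5), consequence = "missense_variant",
                    protein_change = NA_character_, stringsAsFactors = FALSE)
  vs <- make_vs(tab)
  catalog <- data.frame(gene = tab$gene, chrom = tab$chrom, pos = tab$pos,
                        ref = tab$ref, alt = tab$alt, population = "LAT",
                        af = afs, stringsAsFactors = FALSE)
  out <- filter_population_af(vs, catalog, "LAT", 0.05)
  # threshold predicate over {0.001, 0.04, 0.05, 0.051, 0.5}: 3 kept
  expect_equal(n_variants(out), 3L)
  expect_setequal(out$variants$gene, c("A1", "A2", "A3"))

  # absent from the catalogue entirely -> kept (rare by default)
  out2 <- filter_population_af(vs, catalog[0, ], "LAT", 0.05)
  expect_equal(n_variants(out2), 5L)

  # frequency recorded for a different population does not remove
  catalog_other <- catalog
  catalog_other$population <- "NFE"
  expect_equal(n_variants(filter_population_af(vs, catalog_other, "LAT", 0.05)),
               5L)
})

test_that("the cascade composes the three predicates and traces chain", {
  withr::local_seed(99)
  for (rep in 1:25) {
    inp <- rand_cascade_inputs()
    res <- run_cascade(inp$cohort, inp$controls, inp$af)
    # brute-force composition of the three predicates applied independently
    v <- inp$cohort$variants
    keys <- paste(v$chrom, v$pos, v$ref, v$alt)
    coding <- v$consequence %in% alltriage:::DEFAULT_CODING_CONSEQUENCES
    ctrl_keys <- paste(inp$controls$variants$chrom, inp$controls$variants$pos,
                       inp$controls$variants$ref, inp$controls$variants$alt)
    in_ctrl <- keys %in% ctrl_keys
    af_keys <- paste(inp$af$chrom, inp$af$pos, inp$af$ref, inp$af$alt)
    af <- inp$af$af[match(keys, af_keys)]
    common <- !is.na(af) & af > 0.05
    expected <- keys[coding & !in_ctrl & !common]
    got <- paste(res$variants$variants$chrom, res$variants$variants$pos,
                 res$variants$variants$ref, res$variants$variants$alt)
    expect_setequal(got, expected)
    # trace chaining: n_out of stage k = n_in of stage k+1, counts add up
    tr <- res$trace
    expect_equal(tr$n_out, tr$n_in - tr$n_removed)
    expect_equal(tr$n_in[-1], tr$n_out[-nrow(tr)])
  }
})

test_that("a cohort identical to the controls filters to empty", {
  tab <- coding_tab()
  vs <- make_vs(tab)
  res <- run_cascade(vs, vs, data.frame(gene = character(0),
                                        chrom = character(0), pos = integer(0),
                                        ref = character(0), alt = character(0),
                                        population = character(0),
                                        af = numeric(0)))
  expect_equal(n_variants(res$variants), 0L)
})

test_that("cascade is monotone, idempotent and stage-order independent", {
  withr::local_seed(123)
  for (rep in 1:40) {
    inp <- rand_cascade_inputs()
    cfg <- filter_config()
    s1 <- restrict_coding(inp$cohort, cfg$coding_consequences)
    s2 <- subtract_controls(s1, inp$controls)
    s3 <- filter_population_af(s2, inp$af, "LAT", 0.05)
    keyset <- function(x) paste(x$variants$chrom, x$variants$pos,
                                x$variants$ref, x$variants$alt)
    # monotonicity: each stage's output is a subset of its input
    expect_true(all(keyset(s1) %in% keyset(inp$cohort)))
    expect_true(all(keyset(s2) %in% keyset(s1)))
    expect_true(all(keyset(s3) %in% keyset(s2)))
    # order independence of the two independent predicates
    alt <- subtract_controls(filter_population_af(s1, inp$af, "LAT", 0.05),
                             inp$controls)
    expect_setequal(keyset(alt), keyset(s3))
    # idempotence: re-running the cascade removes nothing
    again <- run_cascade(s3, inp$controls, inp$af, cfg)
    expect_equal(n_variants(again$variants), n_variants(s3))
  }
})

test_that("position match mode removes on site identity regardless of allele", {
  tab <- coding_tab()[1, , drop = FALSE]
  vs <- make_vs(tab)  # alt C
  other_allele <- tab
  other_allele$alt <- "G"
  controls <- make_vs(other_allele)
  expect_equal(n_variants(subtract_controls(vs, controls, "allele")), 1L)
  expect_equal(n_variants(subtract_controls(vs, controls, "position")), 0L)
})

test_that("filter_config rejects degenerate settings", {
  expect_error(filter_config(af_threshold = 0),
               class = "alltriage_validation_error")
  expect_error(filter_config(af_threshold = 1),
               class = "alltriage_validation_error")
  expect_error(filter_config(coding_consequences = character(0)),
               class = "alltriage_validation_error")
})
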