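make_panel <- function(dosages, populations = NULL) {
  loci <- data.frame(chrom = "syn_panel", pos = seq_len(ncol(dosages)) * 10L,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_panel(dosages, loci, populations)
}

test_that("common-site intersection keeps exact allele matches in order", {
  withr::local_seed(5)
  dos <- matrix(sample(0:2, 3 * 100, replace = TRUE), nrow = 3,
                dimnames = list(c("a", "b", "c"), NULL))
  panel <- make_panel(dos)
  common <- panel$loci[sample.int(100, 40), ]
  red <- intersect_common_sites(panel, common)
  expect_equal(ncol(red$dosages), 40L)
  # order preserved: positions ascending as in the panel
  expect_true(all(diff(red$loci$pos) > 0))

  # superset leaves the panel unchanged
  full <- intersect_common_sites(panel, panel$loci)
  expect_equal(full$dosages, panel$dosages)

  # disjoint lists raise an informative error
  disjoint <- data.frame(chrom = "other", pos = 1:5, ref = "A", alt = "G")
  expect_error(intersect_common_sites(panel, disjoint),
               class = "alltriage_validation_error")

  # same position, different allele does not match
  flipped <- panel$loci
  flipped$alt <- "T"
  expect_error(intersect_common_sites(panel, flipped),
               class = "alltriage_validation_error")
})

test_that("identity-by-state distances follow the sharing formula", {
  dos <- rbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L), c = c(2L, 1L, 0L))
  d <- genotype_distance_matrix(make_panel(dos))
  expect_equal(d["a", "b"], 0)
  # hand computation: loci share (2-2)/2, (2-0)/2, (2-2)/2 -> mean 1/3 IBS...
  # (0,1,2) vs (2,1,0): per-locus shared fractions 0, 1, 0 -> d = 2/3
  expect_equal(d["a", "c"], 2 / 3)

  dos2 <- rbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 0L))
  d2 <- genotype_distance_matrix(make_panel(dos2))
  # per-locus shared fractions 1, 1, 0 -> d = 1 - 2/3 = 1/3
  expect_equal(d2["a", "b"], 1 / 3)

  # maximal divergence: opposite homozygotes everywhere
  dos3 <- rbind(a = rep(0L, 4), b = rep(2L, 4))
  expect_equal(genotype_distance_matrix(make_panel(dos3))["a", "b"], 1)
})

test_that("distances are symmetric, zero-diagonal and in [0, 1] with missingness", {
  withr::local_seed(17)
  for (rep in 1:10) {
    dos <- matrix(sample(c(0:2, NA), 6 * 30, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), nrow = 6,
                  dimnames = list(paste0("s", 1:6), NULL))
    panel <- make_panel(dos)
    d <- genotype_distance_matrix(panel)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 6))
    expect_true(all(d >= 0 & d <= 1))
  }
  # a pair with no pairwise-complete loci is an error naming the pair
  dos <- rbind(a = c(1L, NA), b = c(NA, 1L))
  expect_error(genotype_distance_matrix(make_panel(dos)), "a.*b",
               class = "alltriage_validation_error")
})

test_that("classical MDS recovers known configurations", {
  # two samples at distance d embed at +/- d/2 on dimension 1
  d <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  mds <- classical_mds(d, k = 1)
  expect_equal(unname(sort(abs(mds$coordinates[, 1]))), c(0.4, 0.4))

  # unit square: recovered up to rigid motion to 1e-8
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  rownames(square) <- paste0("p", 1:4)
  dm <- as.matrix(dist(square))
  mds2 <- classical_mds(dm, k = 2)
  resid <- alltriage:::procrustes_residual(mds2$coordinates, square)
  expect_lt(resid, 1e-8)
  expect_true(mds2$eigenvalues[1] >= mds2$eigenvalues[2])
  expect_true(all(mds2$eigenvalues >= 0))

  # duplicated sample lands on identical coordinates
  pts <- rbind(square, p5 = c(0, 0))
  mds3 <- classical_mds(as.matrix(dist(pts)), k = 2)
  expect_equal(unname(mds3$coordinates["p1", ]),
               unname(mds3$coordinates["p5", ]))

  # invalid inputs
  bad <- dm
  bad[1, 2] <- 9
  expect_error(classical_mds(bad), class = "alltriage_validation_error")
  expect_error(classical_mds(dm, k = 0), class = "alltriage_validation_error")
})

test_that("MDS agrees with the stats::cmdscale oracle on random configurations", {
  withr::local_seed(23)
  for (rep in 1:10) {
    pts <- matrix(rnorm(6 * 3), nrow = 6,
                  dimnames = list(paste0("s", 1:6), NULL))
    dm <- as.matrix(dist(pts))
    ours <- classical_mds(dm, k = 2)
    oracle <- stats::cmdscale(dm, k = 2, eig = TRUE)
    expect_equal(ours$eigenvalues, oracle$eig[1:2], tolerance = 1e-8)
    resid <- alltriage:::procrustes_residual(ours$coordinates, oracle$points,
                                             scale = FALSE)
    expect_lt(resid, 1e-8)
  }
})

test_that("non-Euclidean distances warn and truncate negative eigenvalues", {
  # strong triangle-inequality violations push a negative eigenvalue into
  # the top three of this 5-point dissimilarity
  v <- c(3.79, 0.21, 2.21, 0.57, 1.30, 6.83, 4.86, 3.07, 1.46, 1.22)
  d <- matrix(0, 5, 5, dimnames = list(1:5, 1:5))
  d[lower.tri(d)] <- v
  d <- d + t(d)
  expect_warning(mds <- classical_mds(d, k = 3), "truncated")
  expect_true(all(mds$eigenvalues >= 0))
  expect_equal(mds$eigenvalues[3], 0)
  expect_equal(unname(mds$coordinates[, 3]), rep(0, 5))
})

test_that("the embedding is invariant to sample order up to rigid motion", {
  withr::local_seed(29)
  pts <- matrix(rnorm(8 * 2), nrow = 8, dimnames = list(paste0("s", 1:8), NULL))
  dm <- as.matrix(dist(pts))
  perm <- sample(8)
  m1 <- classical_mds(dm, k = 2)
  m2 <- classical_mds(dm[perm, perm], k = 2)
  resid <- alltriage:::procrustes_residual(
    m2$coordinates[rownames(m1$coordinates), ], m1$coordinates, scale = FALSE)
  expect_lt(resid, 1e-8)
})

test_that("population assignment picks the nearest centroid with tie rules", {
  co <- rbind(r1 = c(0, 0), r2 = c(0, 2), q1 = c(0, 0), q2 = c(0, 1))
  dm <- as.matrix(dist(co))
  mds <- classical_mds(dm, k = 2)
  # use the raw coordinates directly for exact geometry
  mds$coordinates <- co
  pops <- c("AAA", "BBB", NA, NA)
  res <- assign_population(mds, pops)
  a <- res$assignments
  expect_equal(a$assigned[a$sample == "q1"], "AAA")
  expect_equal(a$distance[a$sample == "q1"], 0)
  # equidistant query breaks ties lexicographically and flags ambiguity
  expect_equal(a$assigned[a$sample == "q2"], "AAA")
  expect_true(a$ambiguous[a$sample == "q2"])
  expect_error(assign_population(mds, rep(NA_character_, 4)),
               class = "alltriage_validation_error")
})

test_that("divergent populations separate on dimension 1 and assign correctly", {
  sim <- simulate_ancestry_cohort(n_loci = 500, gap = 0.5, n_ref = 50,
                                  n_query = 20, seed = 424242)
  mds <- ancestry_mds(sim$panel)
  got <- mds$assignments
  acc <- mean(got$assigned[match(sim$truth$sample, got$sample)] ==
                sim$truth$population)
  expect_gte(acc, 0.95)
  # dimension 1 separates the reference populations
  dim1 <- mds$coordinates[, 1]
  a <- dim1[sim$panel$populations %in% "POPA"]
  b <- dim1[sim$panel$populations %in% "POPB"]
  expect_true(max(min(a), min(b)) > min(max(a), max(b)) ||
                abs(mean(a) - mean(b)) > 2 * (sd(a) + sd(b)))
})
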