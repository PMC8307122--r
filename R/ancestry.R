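# ancestry: common-site intersection, identity-by-state distances,
# classical (Torgerson) MDS, nearest-centroid population assignment

#' Construct a genotype panel
#'
#' A samples-by-loci dosage matrix with optional per-sample population
#' labels. Labelled samples act as the reference panel; unlabelled (NA)
#' samples are the queries whose ancestry is inferred.
#'
#' @param dosages numeric matrix, samples in rows, loci in columns, entries
#'   in `{0, 1, 2, NA}`; rownames are sample ids.
#' @param loci data.frame with columns `chrom`, `pos`, `ref`, `alt`, one
#'   row per matrix column (biallelic loci).
#' @param populations optional character vector of population labels, one
#'   per sample (NA for query samples).
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, loci, populations = NULL) {
  if (!is.matrix(dosages) || is.null(rownames(dosages))) {
    stop_alltriage("dosages must be a matrix with sample rownames",
                   "alltriage_validation_error")
  }
  required <- c("chrom", "pos", "ref", "alt")
  if (!all(required %in% names(loci)) || nrow(loci) != ncol(dosages)) {
    stop_alltriage("loci must have chrom/pos/ref/alt, one row per dosage column",
                   "alltriage_validation_error")
  }
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop_alltriage("dosages must lie in {0, 1, 2, NA}",
                   "alltriage_validation_error")
  }
  if (is.null(populations)) {
    populations <- rep(NA_character_, nrow(dosages))
  }
  if (length(populations) != nrow(dosages)) {
    stop_alltriage("populations must have one entry per sample",
                   "alltriage_validation_error")
  }
  rownames(loci) <- NULL
  structure(list(dosages = dosages, loci = loci,
                 populations = as.character(populations)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  labs <- table(x$populations, useNA = "ifany")
  cat(sprintf("<genotype_panel> %d sample(s) x %d locus/loci\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat("  populations:",
      paste(sprintf("%s=%d", ifelse(is.na(names(labs)), "query", names(labs)),
                    as.integer(labs)), collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a genotype panel to a common-variant site list
#'
#' Keeps the loci whose exact (chrom, pos, ref, alt) key appears in the
#' common-sites catalogue, preserving panel order — the step that confines
#' ancestry inference to well-genotyped common polymorphisms.
#'
#' @param panel a [genotype_panel()].
#' @param common_sites `common_sites` catalogue from [read_catalog()].
#' @return The reduced `genotype_panel`.
#' @export
intersect_common_sites <- function(panel, common_sites) {
  pkey <- variant_key(panel$loci$chrom, panel$loci$pos,
                      panel$loci$ref, panel$loci$alt)
  ckey <- variant_key(common_sites$chrom, common_sites$pos,
                      common_sites$ref, common_sites$alt)
  keep <- pkey %in% ckey
  if (!any(keep)) {
    stop_alltriage(
      "no panel loci match the common-sites list; check that both use the same coordinate/allele conventions",
      "alltriage_validation_error")
  }
  genotype_panel(panel$dosages[, keep, drop = FALSE],
                 panel$loci[keep, , drop = FALSE],
                 panel$populations)
}

#' Pairwise genetic distance matrix from genotypes
#'
#' The default metric is one minus identity-by-state (IBS): for samples i
#' and j, IBS is the mean over pairwise-complete loci of
#' `(2 - |d_i - d_j|) / 2`, the fraction of alleles shared at a locus, so
#' the distance lies in \[0, 1\]. Missing genotypes are handled by
#' pairwise-complete averaging, not imputation. An alternative Euclidean
#' metric on column-standardised dosages is available.
#'
#' @param panel a [genotype_panel()] with at least 2 samples and 1 locus.
#' @param metric `"ibs"` (default) or `"euclidean"`.
#' @return Symmetric distance matrix with zero diagonal and sample
#'   dimnames.
#' @export
genotype_distance_matrix <- function(panel, metric = c("ibs", "euclidean")) {
  metric <- match.arg(metric)
  d <- panel$dosages
  n <- nrow(d)
  if (n < 2 || ncol(d) < 1) {
    stop_alltriage("need >= 2 samples and >= 1 locus",
                   "alltriage_validation_error")
  }
  if (metric == "euclidean") {
    z <- scale(d)
    z[, apply(d, 2, function(x) stats::sd(x, na.rm = TRUE) == 0 ||
                all(is.na(x)))] <- 0
    return(as.matrix(stats::dist(z)))
  }
  out <- matrix(0, n, n, dimnames = list(rownames(d), rownames(d)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      complete <- !is.na(d[i, ]) & !is.na(d[j, ])
      if (!any(complete)) {
        stop_alltriage(sprintf(
          "samples %s and %s share no pairwise-complete loci",
          rownames(d)[i], rownames(d)[j]),
          "alltriage_validation_error")
      }
      ibs <- mean((2 - abs(d[i, complete] - d[j, complete])) / 2)
      out[i, j] <- out[j, i] <- 1 - ibs
    }
  }
  out
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a distance matrix in k dimensions by double-centering the matrix
#' of squared distances, B = -1/2 J D^2 J, and taking the top-k
#' eigenvectors scaled by the square roots of their eigenvalues. Negative
#' eigenvalues among the top k (possible for non-Euclidean distances) are
#' truncated at zero with a warning, zeroing the affected coordinate.
#'
#' @param d square symmetric non-negative matrix with zero diagonal.
#' @param k number of dimensions (default 2).
#' @return An object of class `mds_result`: `coordinates` (samples x k
#'   matrix), `eigenvalues` (the k leading values, after truncation),
#'   `all_eigenvalues`, and `assignments` (NULL until
#'   [assign_population()] is applied).
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop_alltriage("distance matrix must be square and symmetric",
                   "alltriage_validation_error")
  }
  if (any(d < 0) || any(abs(diag(d)) > 1e-12)) {
    stop_alltriage("distances must be non-negative with a zero diagonal",
                   "alltriage_validation_error")
  }
  if (k < 1 || k > n - 1) {
    stop_alltriage("k must lie in [1, n_samples - 1]",
                   "alltriage_validation_error")
  }
  d2 <- d^2
  centering <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * centering %*% d2 %*% centering
  b <- (b + t(b)) / 2
  eig <- eigen(b, symmetric = TRUE)
  lambda <- eig$values[seq_len(k)]
  if (any(lambda < -1e-8)) {
    warning(sprintf(
      "negative eigenvalue(s) among the top %d (min %.3g); truncated at zero",
      k, min(lambda)), call. = FALSE)
  }
  lambda_trunc <- pmax(lambda, 0)
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lambda_trunc), nrow = k)
  dimnames(coords) <- list(rownames(d), paste0("dim", seq_len(k)))
  structure(list(coordinates = coords, eigenvalues = lambda_trunc,
                 all_eigenvalues = eig$values, assignments = NULL),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("<mds_result> %d sample(s), %d dimension(s)\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("  leading eigenvalues:",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  if (!is.null(x$assignments)) {
    tab <- table(x$assignments$assigned)
    cat("  assignments:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Plot an MDS embedding
#'
#' Scatter of the first two dimensions, coloured by population label
#' (queries in black).
#'
#' @param x an `mds_result`.
#' @param populations optional label vector aligned with the coordinate
#'   rows.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mds_result <- function(x, populations = NULL, ...) {
  co <- x$coordinates
  if (is.null(populations)) populations <- rep(NA_character_, nrow(co))
  labs <- sort(unique(populations[!is.na(populations)]))
  col <- rep(1L, nrow(co))
  for (i in seq_along(labs)) col[populations %in% labs[i]] <- i + 1L
  graphics::plot(co[, 1], co[, 2], col = col,
                 pch = ifelse(is.na(populations), 4, 19),
                 xlab = "MDS dimension 1", ylab = "MDS dimension 2", ...)
  if (length(labs)) {
    graphics::legend("topright", legend = c(labs, "query"),
                     col = c(seq_along(labs) + 1L, 1L),
                     pch = c(rep(19, length(labs)), 4), bty = "n")
  }
  invisible(x)
}

#' Assign query samples to the nearest reference population
#'
#' Computes the centroid of each labelled reference population in the MDS
#' embedding and assigns every unlabelled (query) sample the label of its
#' nearest centroid. Exact ties break to the lexicographically smallest
#' label and are flagged ambiguous.
#'
#' @param mds an [classical_mds()] result.
#' @param populations character vector of labels aligned with the
#'   coordinate rows; NA marks query samples.
#' @return The `mds_result` with `assignments` filled in: a data.frame
#'   (`sample`, `assigned`, `distance`, `ambiguous`) plus a
#'   `centroid_distances` attribute (queries x populations matrix).
#' @export
assign_population <- function(mds, populations) {
  co <- mds$coordinates
  if (length(populations) != nrow(co)) {
    stop_alltriage("populations must align with the embedding rows",
                   "alltriage_validation_error")
  }
  labs <- sort(unique(populations[!is.na(populations)]))
  if (!length(labs)) {
    stop_alltriage("no labelled reference samples", "alltriage_validation_error")
  }
  centroids <- t(vapply(labs, function(l) {
    colMeans(co[populations %in% l, , drop = FALSE])
  }, numeric(ncol(co))))
  query_idx <- which(is.na(populations))
  qco <- co[query_idx, , drop = FALSE]
  dmat <- matrix(0, nrow = length(query_idx), ncol = length(labs),
                 dimnames = list(rownames(co)[query_idx], labs))
  for (j in seq_along(labs)) {
    diff <- sweep(qco, 2, centroids[j, ])
    dmat[, j] <- sqrt(rowSums(diff^2))
  }
  assigned <- character(length(query_idx))
  distance <- numeric(length(query_idx))
  ambiguous <- logical(length(query_idx))
  for (i in seq_along(query_idx)) {
    dmin <- min(dmat[i, ])
    at_min <- labs[dmat[i, ] <= dmin + 1e-12]
    assigned[i] <- at_min[1]  # labs sorted: lexicographic tie-break
    distance[i] <- dmin
    ambiguous[i] <- length(at_min) > 1
  }
  mds$assignments <- data.frame(
    sample = rownames(co)[query_idx], assigned = assigned,
    distance = distance, ambiguous = ambiguous, stringsAsFactors = FALSE)
  attr(mds$assignments, "centroid_distances") <- dmat
  mds
}

#' End-to-end ancestry inference for a genotype panel
#'
#' Convenience wrapper: optional common-site intersection, genotype
#' distance matrix, classical MDS, and (when the panel has labelled
#' reference samples and unlabelled queries) nearest-centroid population
#' assignment.
#'
#' @param panel a [genotype_panel()] mixing labelled reference samples and
#'   unlabelled queries.
#' @param common_sites optional `common_sites` catalogue.
#' @param k embedding dimensions (default 2, the first two MDS dimensions).
#' @param metric distance metric, see [genotype_distance_matrix()].
#' @return An `mds_result` with assignments when queries are present.
#' @export
ancestry_mds <- function(panel, common_sites = NULL, k = 2,
                         metric = c("ibs", "euclidean")) {
  metric <- match.arg(metric)
  if (!is.null(common_sites)) {
    panel <- intersect_common_sites(panel, common_sites)
  }
  d <- genotype_distance_matrix(panel, metric)
  mds <- classical_mds(d, k = k)
  has_ref <- any(!is.na(panel$populations))
  has_query <- any(is.na(panel$populations))
  if (has_ref && has_query) {
    mds <- assign_population(mds, panel$populations)
  }
  mds
}

# Procrustes residual after optimal translation/rotation/reflection/scaling;
# used in tests to compare embeddings up to rigid motion
procrustes_residual <- function(x, y, scale = TRUE) {
  x <- scale(x, scale = FALSE)
  y <- scale(y, scale = FALSE)
  s <- svd(t(y) %*% x)
  rot <- s$v %*% t(s$u)
  sc <- if (scale) sum(s$d) / sum(x^2) else 1
  sqrt(sum((y - sc * x %*% rot)^2))
}
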