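#' VanRaden kinship matrix
#'
#' VanRaden's method-1 genomic relationship:
#' `K = (X - 2P)(X - 2P)' / (2 * sum(p_k (1 - p_k)))`, with allele
#' frequencies computed from the sample and missing dosages replaced by
#' their expectation `2 p_k`. Negative entries are then set to zero, the
#' usual reporting convention for relative-kinship heatmaps (the
#' standardized GRM used by the EigenGWAS machinery is *not* clamped; see
#' [standardized_grm()]).
#'
#' @param g A [genotypes] object with at least 2 samples and at least one
#'   polymorphic variant.
#' @param clamp_negative Set negative entries to 0 (default `TRUE`).
#' @return Symmetric numeric matrix with sample IDs as dimnames.
#' @export
vanraden_kinship <- function(g, clamp_negative = TRUE) {
  stopifnot(inherits(g, "genotypes"), n_samples(g) >= 2)
  p <- allele_frequency(g)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all variants are monomorphic")
  z <- sweep(g$dosages, 2, 2 * p)      # X - 2P
  z[is.na(z)] <- 0                     # missing -> expectation 2p
  k <- tcrossprod(z) / denom
  if (clamp_negative) k[k < 0] <- 0
  dimnames(k) <- list(g$samples$sample_id, g$samples$sample_id)
  k
}

#' Standardized genomic relationship matrix
#'
#' `A_ij = (1/M) * sum_k (x_ik - 2 p_k)(x_jk - 2 p_k) / (2 p_k (1 - p_k))`
#' over the M variants, with sample-estimated frequencies and missing
#' dosages contributing zero (imputed to `2 p_k`). No clamping: with
#' frequencies computed from the sample, the mean off-diagonal is exactly
#' `-1/(n-1)`. Monomorphic variants are an error (QC them out first).
#'
#' @param g A [genotypes] object.
#' @return Symmetric numeric matrix with sample IDs as dimnames.
#' @export
standardized_grm <- function(g) {
  stopifnot(inherits(g, "genotypes"), n_samples(g) >= 2)
  p <- allele_frequency(g)
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1)) {
    stop("standardized GRM requires every variant polymorphic")
  }
  z <- sweep(g$dosages, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  a <- tcrossprod(z) / n_variants(g)
  dimnames(a) <- list(g$samples$sample_id, g$samples$sample_id)
  a
}

#' Eigendecomposition of a relationship matrix
#'
#' Top-`k` eigenpairs of a (symmetric) GRM, eigenvalues descending.
#' Eigenvector signs are fixed by making each vector's largest-magnitude
#' loading positive, so results are reproducible across BLAS builds.
#' Variance-explained fractions are `eigenvalue / trace`.
#'
#' @param grm Symmetric relationship matrix (e.g. from
#'   [standardized_grm()]).
#' @param k Number of components (default 10; truncated to `n` with a
#'   warning if larger).
#' @return A list of class `grm_pca`: `values` (length `k`), `vectors`
#'   (samples x k, unit norm), `var_explained`, `trace`.
#' @export
grm_pca <- function(grm, k = 10) {
  stopifnot(is.matrix(grm), nrow(grm) == ncol(grm))
  n <- nrow(grm)
  if (k > n) {
    warning("k reduced from ", k, " to ", n)
    k <- n
  }
  e <- eigen(grm, symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- rownames(grm)
  colnames(vec) <- paste0("EV", seq_len(k))
  structure(
    list(values = e$values[seq_len(k)], vectors = vec,
         var_explained = e$values[seq_len(k)] / sum(diag(grm)),
         trace = sum(diag(grm))),
    class = "grm_pca"
  )
}

#' @export
print.grm_pca <- function(x, ...) {
  cat(sprintf("<grm_pca> %d components over %d samples\n",
              length(x$values), nrow(x$vectors)))
  cat("variance explained (%):",
      paste(sprintf("%.2f", 100 * x$var_explained), collapse = " "), "\n")
  invisible(x)
}

#' Rogers' genetic distance between individuals
#'
#' Rogers (1972) distance from individual allele frequencies (0, 1/2, 1 for
#' a diploid): per locus `sqrt(0.5 * sum_alleles (p_a - q_a)^2)`, averaged
#' over the loci where both individuals are called (complete-case per
#' pair). For biallelic loci this is `|x_i - x_j| / 2` on the dosage scale.
#' Values lie in \[0, 1\]; identical genotypes give 0, opposite homozygotes
#' at every locus give 1. Pairs with no shared called locus are `NA`.
#'
#' @param g A [genotypes] object.
#' @return Symmetric numeric matrix (zero diagonal) with sample IDs as
#'   dimnames.
#' @export
rogers_distance <- function(g) {
  stopifnot(inherits(g, "genotypes"), n_samples(g) >= 2)
  x <- g$dosages
  called <- !is.na(x)
  x0 <- x
  x0[!called] <- 0
  storage.mode(x0) <- "double"
  called <- called * 1
  # |xi - xj|/2 summed over shared loci: dosage differences are 0,1,2 so
  # |d| = d^2 only for d in {0,1}; use sum|d| = sum d^2 - 2*#(|d|==2) ... not
  # linear-algebra friendly; instead expand over the three dosage levels.
  n <- nrow(x)
  ind <- lapply(0:2, function(v) (x0 == v & called == 1) * 1)
  shared <- tcrossprod(called)
  # sum over loci of |xi - xj|: |a-b| table over levels {0,1,2}
  absdiff <- matrix(0, n, n)
  w <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  for (a in 1:3) for (b in 1:3) {
    if (w[a, b] > 0) absdiff <- absdiff + w[a, b] * tcrossprod(ind[[a]], ind[[b]])
  }
  d <- (absdiff / 2) / shared
  d[shared == 0] <- NA_real_
  diag(d) <- 0
  d[d < 0] <- 0     # parity with reporting convention; cannot occur here
  dimnames(d) <- list(g$samples$sample_id, g$samples$sample_id)
  if (anyNA(d)) warning("sample pairs with no shared called locus: NA distance")
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on an individual-level
#' distance matrix such as [rogers_distance()]. Negative branch lengths,
#' which NJ can produce on non-additive inputs, are clamped to zero with a
#' message. For an additive matrix the tree reproduces the input path
#' lengths exactly.
#'
#' @param d Square symmetric distance matrix with zero diagonal.
#' @param newick_path Optional path; if given, the tree is also written as
#'   Newick.
#' @return An \pkg{ape} `phylo` object.
#' @export
nj_tree <- function(d, newick_path = NULL) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), all(abs(diag(d)) < 1e-12))
  if (nrow(d) < 3) stop("need at least 3 samples for a neighbor-joining tree")
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    message("clamping ", sum(tr$edge.length < 0), " negative branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  if (!is.null(newick_path)) ape::write.tree(tr, file = newick_path)
  tr
}

#' Panel-level effective statistics from a standardized GRM
#'
#' The mean off-diagonal relatedness `g_bar` measures residual structure;
#' its negative reciprocal `n_e = -1/g_bar` is the effective sample size,
#' and the reciprocal of the off-diagonal variance `m_e = 1/var(g_ij)` is
#' the effective number of independent genome segments.
#'
#' @param grm Matrix from [standardized_grm()] (at least 3 samples).
#' @return Tibble with `mean_offdiag`, `n_e` (`NA` with a warning when the
#'   mean off-diagonal is non-negative), `m_e`.
#' @export
effective_stats <- function(grm) {
  stopifnot(is.matrix(grm), nrow(grm) == ncol(grm))
  if (nrow(grm) < 3) stop("need at least 3 samples")
  off <- grm[lower.tri(grm)]
  g_bar <- mean(off)
  n_e <- if (g_bar < 0) -1 / g_bar else {
    warning("mean off-diagonal relatedness is non-negative; n_e undefined")
    NA_real_
  }
  tibble::tibble(
    mean_offdiag = g_bar,
    n_e = n_e,
    m_e = 1 / stats::var(off)
  )
}
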