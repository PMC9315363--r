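# Vectorised per-SNP simple OLS of a response y on each dosage column,
# complete-case per SNP. Returns beta, se, chi = (beta/se)^2, p (chi-sq 1df).
ols_scan_one <- function(dosages, y) {
  called <- !is.na(dosages)
  x0 <- dosages
  x0[!called] <- 0L
  storage.mode(x0) <- "double"
  m1 <- called * 1
  n_k <- colSums(m1)
  sx <- colSums(x0)
  sxx <- colSums(x0^2)
  sy <- crossprod(m1, y)[, 1]
  syy <- crossprod(m1, y^2)[, 1]
  sxy <- crossprod(x0, y)[, 1]

  sxx_c <- sxx - sx^2 / n_k
  sxy_c <- sxy - sx * sy / n_k
  syy_c <- syy - sy^2 / n_k
  beta <- sxy_c / sxx_c
  sse <- syy_c - beta * sxy_c
  sse[sse < 0] <- 0                      # numerical guard at perfect fit
  se2 <- sse / (n_k - 2) / sxx_c
  chi <- beta^2 / se2
  skip <- n_k < 3 | sxx_c <= 0
  beta[skip] <- NA_real_
  chi[skip] <- NA_real_
  list(beta = unname(beta), se = unname(sqrt(se2)), chi = unname(chi),
       p = unname(stats::pchisq(chi, df = 1, lower.tail = FALSE)))
}

#' Genomic-control inflation factor
#'
#' `lambda_GC = median(chi) / qchisq(0.5, 1)` (the median of a 1-df
#' chi-square, 0.4549364): how far the bulk of the observed association
#' statistics is inflated relative to the null, here by drift and
#' population stratification.
#'
#' @param chi Numeric vector of 1-df chi-square statistics.
#' @return Scalar lambda.
#' @export
lambda_gc <- function(chi) {
  chi <- chi[is.finite(chi)]
  if (length(chi) == 0) stop("no finite chi-square statistics")
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Genomic-control adjusted p-values
#'
#' Deflates each statistic by `lambda` and recomputes the upper-tail 1-df
#' chi-square probability: `p_gc = P(chisq_1 > chi / lambda)`.
#'
#' @param chi Chi-square statistics.
#' @param lambda Genomic-control factor (> 0).
#' @return Adjusted p-values.
#' @export
adjust_p <- function(chi, lambda) {
  stopifnot(lambda > 0)
  stats::pchisq(chi / lambda, df = 1, lower.tail = FALSE)
}

#' EigenGWAS scan: regress GRM eigenvectors on each SNP
#'
#' For each requested eigenvector EV_k of the standardized genomic
#' relationship matrix, fits the per-SNP ordinary least-squares regression
#' `EV_i = mu + beta x_i + e` over the non-missing calls of that SNP,
#' forms the 1-df Wald chi-square `(beta/se)^2` and its p-value, then
#' applies genomic control per eigenvector (lambda from the median
#' chi-square of that EV's scan). SNPs with zero dosage variance on their
#' called samples are skipped (`NA`).
#'
#' @param g A QC-passed [genotypes] object.
#' @param pca A [grm_pca()] result on the same samples (or a GRM matrix,
#'   which will be decomposed).
#' @param evs Integer vector of eigenvector indices (default `1:10`).
#' @return Tibble with `ev`, `name`, `chrom`, `pos`, `beta`, `se`, `chi`,
#'   `p_raw`, `lambda_gc`, `p_gc`, `minus_log10_p_gc`.
#' @export
#' @examples
#' sim <- sim_genotypes(sim_config(n_per_subpop = c(40, 40), n_snps = 500,
#'                                 n_selected = 5, seed = 9))
#' pca <- grm_pca(standardized_grm(sim$genotypes), k = 2)
#' scan <- eigengwas_scan(sim$genotypes, pca, evs = 1)
#' head(dplyr::arrange(scan, p_gc))
eigengwas_scan <- function(g, pca, evs = 1:10) {
  stopifnot(inherits(g, "genotypes"))
  if (is.matrix(pca)) pca <- grm_pca(pca, k = max(evs))
  stopifnot(inherits(pca, "grm_pca"), nrow(pca$vectors) == n_samples(g))
  if (max(evs) > ncol(pca$vectors)) stop("requested EV beyond decomposition")
  purrr::map_dfr(evs, function(k) {
    fit <- ols_scan_one(g$dosages, pca$vectors[, k])
    lam <- lambda_gc(fit$chi)
    p_gc <- adjust_p(fit$chi, lam)
    tibble::tibble(
      ev = k,
      name = g$variants$name, chrom = g$variants$chrom, pos = g$variants$pos,
      beta = fit$beta, se = fit$se, chi = fit$chi, p_raw = fit$p,
      lambda_gc = lam, p_gc = p_gc,
      minus_log10_p_gc = -log10(p_gc)
    )
  })
}

#' Permutation significance threshold for an EigenGWAS scan
#'
#' Shuffles the chosen eigenvector across samples `n_perm` times; each
#' permutation reruns the full per-SNP scan, applies its own
#' within-permutation genomic control, and records the most significant
#' `p_gc`. The threshold is the `1 - quantile` (default 5th) percentile of
#' those minimum p-values, returned as `-log10(p)`: by construction about
#' 5% of null scans produce something more extreme.
#'
#' @param g A [genotypes] object.
#' @param pca A [grm_pca()] result for the same samples.
#' @param ev Eigenvector index to permute (default 1).
#' @param n_perm Number of permutations (default 1000).
#' @param quantile Coverage of the threshold (default 0.95).
#' @param seed Integer seed for the permutations.
#' @return List with `threshold` (-log10 scale), `min_p` (the permutation
#'   minima), `n_perm`.
#' @export
permutation_threshold <- function(g, pca, ev = 1, n_perm = 1000,
                                  quantile = 0.95, seed = 1L) {
  stopifnot(inherits(g, "genotypes"), inherits(pca, "grm_pca"),
            n_perm >= 100)
  set.seed(seed)
  y <- pca$vectors[, ev]
  min_p <- vapply(seq_len(n_perm), function(i) {
    fit <- ols_scan_one(g$dosages, sample(y))
    lam <- lambda_gc(fit$chi)
    min(adjust_p(fit$chi, lam), na.rm = TRUE)
  }, numeric(1))
  thr_p <- stats::quantile(min_p, probs = 1 - quantile, names = FALSE,
                           type = 7)
  list(threshold = -log10(thr_p), min_p = min_p, n_perm = n_perm)
}

#' Filter an EigenGWAS scan to significant records
#'
#' @param scan Tibble from [eigengwas_scan()].
#' @param cutoff Significance cutoff on the `-log10(p_gc)` scale
#'   (default 5.0); records at or above it are kept.
#' @return The significant subset of `scan`.
#' @export
select_significant <- function(scan, cutoff = 5.0) {
  dplyr::filter(scan, !is.na(.data$minus_log10_p_gc),
                .data$minus_log10_p_gc >= cutoff)
}

#' Merge significant SNPs into candidate selection regions
#'
#' Within each eigenvector and chromosome, significant SNPs whose +/-
#' `flank_bp` windows overlap are merged transitively into one region
#' spanning `[min pos - flank, max pos + flank]` (floored at 0), reported
#' in Mb to 2 decimals. The representative SNP is the one with the largest
#' `-log10(p_gc)` (ties: smaller position), and its per-SNP F_ST is
#' attached when a table from [wc_fst_per_snp()] is supplied. Regions from
#' different EVs are kept separate; `n_unique_regions` counts them after
#' collapsing cross-EV overlaps per chromosome.
#'
#' @param significant Tibble from [select_significant()].
#' @param flank_bp Flank added on both sides of each SNP (default 5 Mb).
#' @param per_snp_fst Optional tibble from [wc_fst_per_snp()] (columns
#'   `name`, `theta`).
#' @return List with `regions` (tibble: ev, chrom, start_mb, end_mb,
#'   top_snp, top_pos, minus_log10_p_gc, fst, n_snps) and
#'   `n_unique_regions`.
#' @export
merge_regions <- function(significant, flank_bp = 5e6, per_snp_fst = NULL) {
  if (nrow(significant) == 0) {
    return(list(regions = tibble::tibble(
      ev = integer(), chrom = character(), start_mb = numeric(),
      end_mb = numeric(), top_snp = character(), top_pos = integer(),
      minus_log10_p_gc = numeric(), fst = numeric(), n_snps = integer()
    ), n_unique_regions = 0L))
  }
  sig <- dplyr::arrange(significant, .data$ev, .data$chrom, .data$pos)
  regions <- sig |>
    dplyr::group_by(.data$ev, .data$chrom) |>
    dplyr::group_modify(function(d, key) {
      gap_new <- c(TRUE, diff(d$pos) > 2 * flank_bp)
      d$region <- cumsum(gap_new)
      d |>
        dplyr::group_by(.data$region) |>
        dplyr::group_modify(function(r, k2) {
          top <- r[order(-r$minus_log10_p_gc, r$pos), ][1, ]
          tibble::tibble(
            start_mb = round(max(min(r$pos) - flank_bp, 0) / 1e6, 2),
            end_mb = round((max(r$pos) + flank_bp) / 1e6, 2),
            top_snp = top$name, top_pos = top$pos,
            minus_log10_p_gc = top$minus_log10_p_gc,
            n_snps = nrow(r)
          )
        }) |>
        dplyr::ungroup() |>
        dplyr::select(-"region")
    }) |>
    dplyr::ungroup()
  if (!is.null(per_snp_fst)) {
    regions$fst <- per_snp_fst$theta[match(regions$top_snp, per_snp_fst$name)]
  } else {
    regions$fst <- NA_real_
  }
  regions <- regions[, c("ev", "chrom", "start_mb", "end_mb", "top_snp",
                         "top_pos", "minus_log10_p_gc", "fst", "n_snps")]

  # cross-EV unique regions: size of the interval union per chromosome
  count_union <- function(start, end) {
    o <- order(start)
    start <- start[o]; end <- end[o]
    k <- 1L
    hi <- end[1]
    for (i in seq_along(start)[-1]) {
      if (start[i] > hi) {
        k <- k + 1L
        hi <- end[i]
      } else hi <- max(hi, end[i])
    }
    k
  }
  n_unique <- regions |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(n = count_union(.data$start_mb, .data$end_mb),
                     .groups = "drop") |>
    dplyr::pull(.data$n) |>
    sum()
  list(regions = regions, n_unique_regions = as.integer(n_unique))
}
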