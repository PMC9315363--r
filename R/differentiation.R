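# Weir & Cockerham (1984) per-locus variance components a, b, c for r
# groups, computed from per-group sample sizes, ALT frequencies and
# heterozygote fractions. Everything is vectorised over loci.
wc_components <- function(n_mat, p_mat, h_mat) {
  r <- nrow(n_mat)
  n_tot <- colSums(n_mat)
  n_bar <- n_tot / r
  nc <- (n_tot - colSums(n_mat^2) / n_tot) / (r - 1)
  p_bar <- colSums(n_mat * p_mat) / n_tot
  s2 <- colSums(n_mat * sweep(p_mat, 2, p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- colSums(n_mat * h_mat) / n_tot

  a <- (n_bar / nc) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  c <- h_bar / 2
  list(a = a, b = b, c = c, p_bar = p_bar)
}

# per-group n, p, het for the variants of g restricted to groups `use`
group_freqs <- function(g, use = NULL) {
  sp <- subpops(g)
  groups <- if (is.null(use)) sort(unique(sp)) else use
  dos <- g$dosages
  n_mat <- p_mat <- h_mat <- matrix(NA_real_, length(groups), ncol(dos))
  for (i in seq_along(groups)) {
    d <- dos[sp == groups[i], , drop = FALSE]
    n <- colSums(!is.na(d))
    n_mat[i, ] <- n
    p_mat[i, ] <- ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA)
    h_mat[i, ] <- ifelse(n > 0, colSums(d == 1L, na.rm = TRUE) / n, NA)
  }
  list(groups = groups, n = n_mat, p = p_mat, h = h_mat)
}

#' Per-SNP Weir-Cockerham F_ST
#'
#' Weir & Cockerham's (1984) moment estimator `theta = a / (a + b + c)` per
#' SNP across two or more subpopulations, using per-group sample sizes,
#' allele frequencies and observed heterozygote fractions (complete-case
#' per SNP). SNPs monomorphic across all groups (or with a group having
#' fewer than 2 called individuals) are reported as `NA`, not 0; negative
#' per-SNP estimates are kept raw.
#'
#' @param g A [genotypes] object with at least 2 subpopulations.
#' @param groups Optional character vector restricting to a subset of
#'   subpopulation labels.
#' @return Tibble with columns `name`, `chrom`, `pos`, `a`, `b`, `c`,
#'   `theta`.
#' @export
wc_fst_per_snp <- function(g, groups = NULL) {
  stopifnot(inherits(g, "genotypes"))
  gf <- group_freqs(g, groups)
  if (length(gf$groups) < 2) stop("need at least 2 subpopulations")
  comp <- wc_components(gf$n, gf$p, gf$h)
  denom <- comp$a + comp$b + comp$c
  bad <- apply(gf$n < 2, 2, any) | comp$p_bar <= 0 | comp$p_bar >= 1 |
    !is.finite(denom) | denom == 0
  theta <- ifelse(bad, NA_real_, comp$a / denom)
  tibble::tibble(
    name = g$variants$name, chrom = g$variants$chrom, pos = g$variants$pos,
    a = comp$a, b = comp$b, c = comp$c, theta = theta
  )
}

#' Multi-locus (pairwise) Weir-Cockerham F_ST
#'
#' Ratio-of-sums estimator `sum(a) / sum(a + b + c)` over loci, for one
#' pair (or any set) of subpopulations, with an optional permutation test
#' obtained by shuffling group labels among the involved samples.
#'
#' @param g A [genotypes] object.
#' @param pair Character vector of 2+ subpopulation labels (default: all).
#' @param n_perm Number of label permutations for the p-value (0 = none).
#' @return Tibble with `fst` and, when permuted, `p_perm`.
#' @export
pairwise_fst <- function(g, pair = NULL, n_perm = 0) {
  stopifnot(inherits(g, "genotypes"))
  if (is.null(pair)) pair <- sort(unique(subpops(g)))
  sub <- g[subpops(g) %in% pair, ]
  obs <- fst_ratio_of_sums(sub)
  if (n_perm <= 0) return(tibble::tibble(fst = obs))
  labs <- subpops(sub)
  perm <- replicate(n_perm, {
    sub$samples$subpop <- sample(labs)
    fst_ratio_of_sums(sub)
  })
  tibble::tibble(fst = obs, p_perm = (1 + sum(perm >= obs)) / (1 + n_perm))
}

fst_ratio_of_sums <- function(g) {
  gf <- group_freqs(g)
  comp <- wc_components(gf$n, gf$p, gf$h)
  ok <- apply(gf$n >= 2, 2, all) & comp$p_bar > 0 & comp$p_bar < 1
  sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
}

#' All pairwise F_ST values between subpopulations
#'
#' @inheritParams pairwise_fst
#' @return Tibble with `pop1`, `pop2`, `fst` (and `p_perm` if permuted),
#'   one row per unordered pair.
#' @export
pairwise_fst_matrix <- function(g, n_perm = 0) {
  pops <- sort(unique(subpops(g)))
  stopifnot(length(pops) >= 2)
  pairs <- utils::combn(pops, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    dplyr::bind_cols(
      tibble::tibble(pop1 = pairs[1, i], pop2 = pairs[2, i]),
      pairwise_fst(g, pairs[, i], n_perm = n_perm)
    )
  })
}

# Per-locus AMOVA sums of squares at the allele level. For a biallelic
# locus with pooled frequency p over 2N alleles:
#   SS_total  = 2N p (1-p)          (binary allele values)
#   SS_among  = sum_g 2 n_g (p_g - p)^2
#   SS_within_individuals = n_het / 2  (the two alleles of a het differ)
amova_ss <- function(g) {
  gf <- group_freqs(g)
  n_mat <- gf$n
  p_mat <- gf$p
  n_tot <- colSums(n_mat)
  p_bar <- colSums(n_mat * p_mat) / n_tot
  ss_total <- 2 * n_tot * p_bar * (1 - p_bar)
  ss_among <- colSums(2 * n_mat * sweep(p_mat, 2, p_bar)^2)
  n_het <- colSums(g$dosages == 1L, na.rm = TRUE)
  ss_wi <- n_het / 2
  ok <- is.finite(ss_total)
  c(
    among = sum(ss_among[ok]),
    within_ind = sum(ss_wi[ok]),
    total = sum(ss_total[ok])
  )
}

#' Three-level analysis of molecular variance (AMOVA)
#'
#' Excoffier-style hierarchical decomposition of allele-level squared
#' differences into among-subpopulation, among-individuals-within-
#' subpopulation, and within-individual components, for unphased biallelic
#' dosages (each diploid contributes two allele values per locus; the
#' squared molecular distance is the number of allele differences).
#' Degrees of freedom follow the standard pattern `(G - 1, N - G, N)`.
#' Variance components come from the mean squares:
#' `Vc = MS_within`, `Vb = (MS_among_ind - Vc) / 2`,
#' `Va = (MS_among_pop - MS_among_ind) / (2 n_c)` with
#' `n_c = (N - sum(n_g^2)/N) / (G - 1)`. Permutation p-values shuffle
#' whole individuals across subpopulations.
#'
#' @param g A [genotypes] object with >= 2 subpopulations.
#' @param n_perm Number of permutations (default 1000; 0 = none).
#' @return A list of class `amova` with `table` (tibble: source, df, ss,
#'   variance, pct_variation, p_perm) and `totals`.
#' @export
#' @examples
#' sim <- sim_genotypes(sim_config(n_per_subpop = c(15, 15, 15),
#'                                 n_snps = 200, seed = 11))
#' amova(sim$genotypes, n_perm = 99)
amova <- function(g, n_perm = 1000) {
  stopifnot(inherits(g, "genotypes"))
  sp <- subpops(g)
  pops <- unique(sp)
  n_g <- as.numeric(table(sp)[pops])
  big_g <- length(pops)
  n <- n_samples(g)
  if (big_g < 2) stop("need at least 2 subpopulations")

  decompose <- function(panel) {
    ss <- amova_ss(panel)
    ss_ai <- ss[["total"]] - ss[["among"]] - ss[["within_ind"]]
    df <- c(big_g - 1, n - big_g, n)
    ms <- c(ss[["among"]], ss_ai, ss[["within_ind"]]) / df
    tab <- table(subpops(panel))
    n_c <- (n - sum(tab^2) / n) / (big_g - 1)
    vc <- ms[3]
    vb <- (ms[2] - vc) / 2
    va <- (ms[1] - ms[2]) / (2 * n_c)
    list(ss = c(ss[["among"]], ss_ai, ss[["within_ind"]]),
         df = df, v = c(va, vb, vc))
  }
  obs <- decompose(g)
  p_perm <- rep(NA_real_, 3)
  if (n_perm > 0) {
    exceed <- c(0, 0, 0)
    gp <- g
    for (i in seq_len(n_perm)) {
      gp$samples$subpop <- sample(sp)
      v <- decompose(gp)$v
      exceed <- exceed + (v >= obs$v)
    }
    p_perm <- (1 + exceed) / (1 + n_perm)
  }
  v_tot <- sum(obs$v)
  structure(
    list(
      table = tibble::tibble(
        source = c("Among subpopulations",
                   "Among individuals within subpopulations",
                   "Within individuals"),
        df = obs$df, ss = obs$ss, variance = obs$v,
        pct_variation = 100 * obs$v / v_tot,
        p_perm = p_perm
      ),
      totals = tibble::tibble(df = sum(obs$df), ss = sum(obs$ss),
                              variance = v_tot)
    ),
    class = "amova"
  )
}

#' @export
print.amova <- function(x, ...) {
  cat("Analysis of molecular variance\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  cat(sprintf("Total: df %d, SS %.2f, variance %.4f\n",
              x$totals$df, x$totals$ss, x$totals$variance))
  invisible(x)
}
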