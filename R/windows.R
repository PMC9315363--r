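#' Per-site nucleotide diversity
#'
#' For a biallelic site with `n = 2 * n_called` haplotypes of which `j`
#' carry the ALT allele, the average pairwise difference is
#' `pi = 2 j (n - j) / (n (n - 1))`. Sites with fewer than two haplotypes
#' are undefined (`NA`).
#'
#' @param g A [genotypes] object, dosage matrix, or single dosage vector.
#' @return Numeric vector, one per-site pi value per variant.
#' @export
#' @examples
#' site_pi(c(0, 1, 2))   # n = 6 haplotypes, j = 3
site_pi <- function(g) {
  x <- if (inherits(g, "genotypes")) g$dosages else g
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- 2 * colSums(!is.na(x))
  j <- colSums(x, na.rm = TRUE)
  out <- ifelse(n >= 2, 2 * j * (n - j) / (n * (n - 1)), NA_real_)
  unname(out)
}

# Tajima (1989) constants for n haplotypes
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D for a set of segregating sites
#'
#' Standardised difference between the mean pairwise diversity and
#' Watterson's estimator: `D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S - 1))`
#' with the usual constants computed from the haplotype count `n`.
#' Undefined (`NA`) when `S = 0` or the variance term is non-positive.
#'
#' @param pi_sum Sum of per-site pi over the `S` sites (count scale).
#' @param s Number of segregating sites.
#' @param n Number of haplotypes (>= 4).
#' @return Tajima's D, or `NA` when undefined.
#' @export
tajimas_d <- function(pi_sum, s, n) {
  if (s < 1 || n < 4) return(NA_real_)
  k <- tajima_constants(n)
  v <- k$e1 * s + k$e2 * s * (s - 1)
  if (v <= 0) return(NA_real_)
  (pi_sum - s / k$a1) / sqrt(v)
}

#' Sliding-window nucleotide diversity and Tajima's D
#'
#' Tiles each chromosome with windows of `window` bp advanced by `step` bp,
#' anchored at position 1; the final partial window is retained. Window pi
#' is the sum of per-site pi over the SNPs in the window divided by the
#' window length in bp (so empty windows have `pi = 0`). Tajima's D uses the
#' SNP count `S` in the window and `n = 2 *` (rounded mean non-missing
#' sample count over the window's SNPs); it is `NA` for empty windows.
#' With `by_subpop = TRUE` all statistics are recomputed within each
#' subpopulation as well as for the whole panel (`group = "WP"`).
#'
#' @param g A [genotypes] object.
#' @param window Window size in bp (default 1e6, i.e. 1,000 kb).
#' @param step Step size in bp (default 1e5, i.e. 100 kb).
#' @param by_subpop Also compute per-subpopulation tracks.
#' @return Tibble with columns `group`, `chrom`, `start`, `end` (1-based
#'   inclusive), `n_snps`, `pi`, `tajima_d`.
#' @export
#' @examples
#' sim <- sim_genotypes(sim_config(n_per_subpop = c(25, 25), n_snps = 300,
#'                                 seed = 3))
#' windowed_stats(sim$genotypes, window = 1e6, step = 5e5)
windowed_stats <- function(g, window = 1e6, step = 1e5, by_subpop = FALSE) {
  stopifnot(inherits(g, "genotypes"), window >= step, step > 0)
  scan_one <- function(sub, label) {
    sp <- site_pi(sub)
    n_called <- colSums(!is.na(sub$dosages))
    v <- sub$variants
    out <- list()
    for (ch in unique(v$chrom)) {
      sel <- which(v$chrom == ch)
      pos <- v$pos[sel]
      max_pos <- max(pos)
      starts <- seq(1, max_pos, by = step)
      ends <- starts + window - 1                    # full nominal window
      n_win <- length(starts)
      idx_start <- findInterval(starts - 1, pos) + 1   # first pos >= start
      idx_end <- findInterval(ends, pos)               # last pos <= end
      n_snps <- pmax(idx_end - idx_start + 1, 0)
      csum_pi <- c(0, cumsum(sp[sel]))
      csum_n <- c(0, cumsum(n_called[sel]))
      pi_sum <- ifelse(n_snps > 0,
                       csum_pi[idx_end + 1] - csum_pi[idx_start], 0)
      ncall_sum <- ifelse(n_snps > 0,
                          csum_n[idx_end + 1] - csum_n[idx_start], 0)
      taj <- rep(NA_real_, n_win)
      for (w in which(n_snps > 0)) {
        n_hap <- 2 * round(ncall_sum[w] / n_snps[w])
        taj[w] <- tajimas_d(pi_sum[w], n_snps[w], n_hap)
      }
      out[[ch]] <- tibble::tibble(
        group = label, chrom = ch,
        start = as.numeric(starts), end = as.numeric(ends),
        n_snps = as.integer(n_snps),
        pi = pi_sum / window, tajima_d = taj
      )
    }
    dplyr::bind_rows(out)
  }
  res <- scan_one(g, "WP")
  if (by_subpop) {
    for (sp in sort(unique(subpops(g)))) {
      res <- dplyr::bind_rows(res, scan_one(g[subpops(g) == sp, ], sp))
    }
  }
  res
}
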