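# small hand-built genotype panels used across tests

make_panel <- function(dosages, chrom = NULL, pos = NULL,
                       subpop = NULL, ref = "A", alt = "G") {
  m <- ncol(dosages)
  n <- nrow(dosages)
  genotypes(
    dosages = dosages,
    variants = data.frame(
      chrom = chrom %||% rep("1A", m),
      pos = pos %||% (seq_len(m) * 1000L),
      ref = rep_len(ref, m), alt = rep_len(alt, m)
    ),
    samples = data.frame(
      sample_id = sprintf("s%03d", seq_len(n)),
      subpop = subpop %||% rep("P1", n)
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent scalar Weir-Cockerham (1984) oracle for one locus:
# counts per group of the three genotype classes (n0, n1, n2)
wc_oracle_locus <- function(counts) {
  r <- nrow(counts)
  n_i <- rowSums(counts)
  p_i <- (counts[, 3] * 2 + counts[, 2]) / (2 * n_i)
  h_i <- counts[, 2] / n_i
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# independent Tajima's D oracle from a dosage matrix (no missing data)
tajima_oracle <- function(dos) {
  n <- 2 * nrow(dos)
  j <- colSums(dos)
  seg <- j > 0 & j < n
  s <- sum(seg)
  if (s == 0) return(NA_real_)
  pi_sum <- sum(sapply(j[seg], function(jj) {
    # average pairwise differences among n haplotypes at one site
    jj * (n - jj) / choose(n, 2)
  }))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}
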