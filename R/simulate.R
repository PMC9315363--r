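#' Approximate chromosome lengths for hexaploid bread wheat (bp)
#'
#' Lengths close to the IWGSC RefSeq v1.0 assembly, used as default variant
#' placement space by [sim_config()].
#'
#' @return Tibble with columns `chrom` and `length_bp`.
#' @export
wheat_chromosomes <- function() {
  mb <- c(
    `1A` = 594, `1B` = 689, `1D` = 495,
    `2A` = 781, `2B` = 801, `2D` = 651,
    `3A` = 750, `3B` = 830, `3D` = 615,
    `4A` = 744, `4B` = 673, `4D` = 509,
    `5A` = 709, `5B` = 713, `5D` = 566,
    `6A` = 618, `6B` = 720, `6D` = 473,
    `7A` = 736, `7B` = 750, `7D` = 638
  )
  tibble::tibble(chrom = names(mb), length_bp = as.numeric(mb) * 1e6)
}

#' Simulation configuration for the Balding-Nichols genotype generator
#'
#' Defaults emulate a selfing hexaploid-wheat diversity panel: three
#' subpopulations of 145/128/149 accessions, 10,000 biallelic SNPs on 21
#' chromosomes with genome-imbalanced density (B > A >> D), weak
#' subpopulation divergence (drift F around the 0.05-0.075 range typical of
#' such panels), strong residual inbreeding, and a handful of strongly
#' differentiated "selected" loci.
#'
#' @param n_per_subpop Integer vector, samples per subpopulation.
#' @param n_snps Total number of biallelic SNPs.
#' @param chromosomes Tibble with `chrom`, `length_bp` (see
#'   [wheat_chromosomes()]).
#' @param genome_share Named numeric, fraction of SNPs per subgenome
#'   (A/B/D); within a subgenome SNP counts are proportional to chromosome
#'   length. Ignored (uniform on length) if any chromosome is unmapped.
#' @param fst_drift Balding-Nichols drift parameter F in (0, 1).
#' @param n_selected Number of selected loci with extra divergence.
#' @param selected_delta Extra allele-frequency shift in (0, 1] applied to
#'   subpopulation 1 at selected loci (shifted across 0.5, clipped to
#'   \[0.01, 0.99\]).
#' @param selfing_het Heterozygote retention s in \[0, 1): the heterozygote
#'   class is deflated to `s * 2pq` (inbreeding coefficient `1 - s`).
#' @param missing_rate Fraction of calls set missing, uniformly at random.
#' @param maf_floor Ancestral minor-allele-frequency floor in (0, 0.5).
#' @param seed Integer seed; the whole simulation is a pure function of the
#'   config including this seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_subpop = c(145L, 128L, 149L),
                       n_snps = 10000L,
                       chromosomes = wheat_chromosomes(),
                       genome_share = c(A = 0.40, B = 0.49, D = 0.11),
                       fst_drift = 0.06,
                       n_selected = 20L,
                       selected_delta = 0.5,
                       selfing_het = 0.05,
                       missing_rate = 0.02,
                       maf_floor = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_per_subpop = as.integer(n_per_subpop), n_snps = as.integer(n_snps),
    chromosomes = tibble::as_tibble(chromosomes),
    genome_share = genome_share,
    fst_drift = fst_drift, n_selected = as.integer(n_selected),
    selected_delta = selected_delta, selfing_het = selfing_het,
    missing_rate = missing_rate, maf_floor = maf_floor,
    seed = as.integer(seed)
  )
  stopifnot(
    length(cfg$n_per_subpop) >= 1, all(cfg$n_per_subpop > 0),
    cfg$n_snps >= 1, cfg$n_snps >= cfg$n_selected, cfg$n_selected >= 0,
    all(c("chrom", "length_bp") %in% names(cfg$chromosomes)),
    all(cfg$chromosomes$length_bp > 0),
    cfg$fst_drift > 0, cfg$fst_drift < 1,
    cfg$selected_delta > 0, cfg$selected_delta <= 1,
    cfg$selfing_het >= 0, cfg$selfing_het < 1,
    cfg$missing_rate >= 0, cfg$missing_rate < 0.5
  )
  if (!(cfg$maf_floor > 0 && cfg$maf_floor < 0.5)) {
    stop("maf_floor must lie strictly between 0 and 0.5")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Draw ancestral allele frequencies
#'
#' Frequencies are Uniform(`maf_floor`, `1 - maf_floor`), matching the
#' post-QC support of a MAF-filtered panel, so every locus satisfies
#' `min(p, 1 - p) >= maf_floor`.
#'
#' @param n_snps Number of loci.
#' @param maf_floor Minor-allele-frequency floor, in (0, 0.5).
#' @param rng_seed Optional integer seed (used via a local RNG scope).
#' @return Numeric vector of length `n_snps`.
#' @export
sim_ancestral_freqs <- function(n_snps, maf_floor = 0.05, rng_seed = NULL) {
  if (!(maf_floor > 0 && maf_floor < 0.5)) {
    stop("maf_floor must lie strictly between 0 and 0.5")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  stats::runif(n_snps, maf_floor, 1 - maf_floor)
}

# SNP counts per chromosome: subgenome shares split by length within genome
snps_per_chromosome <- function(chromosomes, genome_share, n_snps) {
  gen <- genome_of(chromosomes$chrom)
  if (any(gen == "UNMAPPED") || is.null(genome_share)) {
    w <- chromosomes$length_bp / sum(chromosomes$length_bp)
  } else {
    w <- numeric(nrow(chromosomes))
    for (g in unique(gen)) {
      sel <- gen == g
      w[sel] <- genome_share[[g]] *
        chromosomes$length_bp[sel] / sum(chromosomes$length_bp[sel])
    }
    w <- w / sum(w)
  }
  counts <- floor(w * n_snps)
  # distribute the remainder by largest fractional part, ties to first
  rem <- n_snps - sum(counts)
  if (rem > 0) {
    frac <- w * n_snps - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

# Ts/Tv-realistic ref/alt pairs (transition-heavy, as in GBS SNP panels)
draw_alleles <- function(n) {
  classes <- c("A/G", "C/T", "A/T", "A/C", "G/T", "C/G")
  probs <- c(0.3644, 0.3680, 0.0367, 0.0656, 0.0630, 0.1022)
  cls <- sample(classes, n, replace = TRUE, prob = probs)
  pair <- strsplit(cls, "/", fixed = TRUE)
  swap <- stats::runif(n) < 0.5
  ref <- vapply(pair, `[`, "", 1L)
  alt <- vapply(pair, `[`, "", 2L)
  tmp <- ref[swap]; ref[swap] <- alt[swap]; alt[swap] <- tmp
  list(ref = ref, alt = alt)
}

#' Simulate a structured, selfing genotype panel (Balding-Nichols model)
#'
#' For each locus with ancestral frequency `p`, each subpopulation's
#' frequency is drawn from the Balding-Nichols distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` (mean `p`, variance `F p (1-p)`) with
#' `F = fst_drift`. At the `n_selected` selected loci, subpopulation 1's
#' frequency is additionally shifted by `selected_delta` across 0.5
#' (upward when below 0.5, downward otherwise) and clipped to
#' \[0.01, 0.99\], so the realised extra divergence is close to
#' `selected_delta` at every selected locus.
#' Genotypes are drawn per individual from the partial-selfing model
#' `P(het) = s * 2pq`, `P(hom) = p^2 + (1-s) p q` (each side), then a
#' `missing_rate` fraction of calls is masked completely at random.
#' Variants are placed at sorted uniform positions on the configured
#' chromosomes and named `chrom_pos`.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements:
#'   * `genotypes`: a [genotypes] object (subpopulations `POP1`, `POP2`, ...);
#'   * `truth`: tibble of all loci with ancestral and per-subpopulation
#'     frequencies and a `selected` flag.
#' @export
#' @examples
#' sim <- sim_genotypes(sim_config(n_per_subpop = c(30, 30), n_snps = 200,
#'                                 n_selected = 2, seed = 42))
#' sim$genotypes
#' dplyr::filter(sim$truth, selected)
sim_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pop <- length(config$n_per_subpop)
  n <- sum(config$n_per_subpop)
  m <- config$n_snps
  f <- config$fst_drift
  s <- config$selfing_het

  p_anc <- sim_ancestral_freqs(m, config$maf_floor)

  # subpopulation frequencies: Balding-Nichols beta draws
  p_sub <- matrix(NA_real_, n_pop, m)
  for (k in seq_len(n_pop)) {
    p_sub[k, ] <- stats::rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }
  # numerical guard: beta draws can hit 0/1 exactly at small shapes
  p_sub <- pmin(pmax(p_sub, 1e-6), 1 - 1e-6)

  selected <- rep(FALSE, m)
  if (config$n_selected > 0) {
    idx <- sample.int(m, config$n_selected)
    selected[idx] <- TRUE
    p1 <- p_sub[1, idx]
    # shift across 0.5 so the realised divergence is (close to) delta itself;
    # shifting toward the nearer boundary would clip most loci to a tiny shift
    shift <- ifelse(p1 < 0.5, config$selected_delta, -config$selected_delta)
    p_sub[1, idx] <- pmin(pmax(p1 + shift, 0.01), 0.99)
  }

  # genotype draws per subpopulation block (partial selfing, F_IS = 1 - s)
  dos <- matrix(NA_integer_, n, m)
  row0 <- 0L
  for (k in seq_len(n_pop)) {
    nk <- config$n_per_subpop[k]
    p <- p_sub[k, ]
    q <- 1 - p
    p_het <- s * 2 * p * q
    p_alt <- p^2 + (1 - s) * p * q     # hom ALT
    u <- matrix(stats::runif(nk * m), nk, m)
    gk <- matrix(0L, nk, m)
    gk[u < rep(p_het, each = nk)] <- 1L
    hom <- u >= rep(p_het, each = nk) & u < rep(p_het + p_alt, each = nk)
    gk[hom] <- 2L
    dos[row0 + seq_len(nk), ] <- gk
    row0 <- row0 + nk
  }
  if (config$missing_rate > 0) {
    dos[stats::runif(n * m) < config$missing_rate] <- NA_integer_
  }

  # variant placement: sorted uniform positions per chromosome
  counts <- snps_per_chromosome(config$chromosomes, config$genome_share, m)
  chrom <- rep(config$chromosomes$chrom, counts)
  pos <- unlist(lapply(seq_len(nrow(config$chromosomes)), function(i) {
    sort(sample.int(config$chromosomes$length_bp[i], counts[i]))
  }))
  al <- draw_alleles(m)
  variants <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                             ref = al$ref, alt = al$alt)
  samples <- tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(n)),
    subpop = rep(paste0("POP", seq_len(n_pop)), config$n_per_subpop)
  )
  g <- genotypes(dos, variants, samples)

  # truth table follows the sorted variant order of the container
  ord <- order(variants$chrom, variants$pos)
  freq <- t(p_sub)[ord, , drop = FALSE]
  colnames(freq) <- paste0("freq_POP", seq_len(n_pop))
  truth <- tibble::tibble(
    name = g$variants$name, chrom = g$variants$chrom, pos = g$variants$pos,
    p_ancestral = p_anc[ord], selected = selected[ord]
  )
  truth <- dplyr::bind_cols(truth, tibble::as_tibble(freq))
  list(genotypes = g, truth = truth)
}
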