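test_that("VanRaden kinship matches a hand-computed 3x2 fixture", {
  dos <- rbind(s1 = c(0L, 2L), s2 = c(1L, 1L), s3 = c(2L, 0L))
  g <- make_panel(dos, pos = c(100L, 200L))
  p <- c(0.5, 0.5)
  z <- sweep(dos, 2, 2 * p)
  k_manual <- z %*% t(z) / (2 * sum(p * (1 - p)))
  k <- vanraden_kinship(g, clamp_negative = FALSE)
  expect_equal(unname(k), unname(k_manual))
  k_clamped <- vanraden_kinship(g)
  expect_true(all(k_clamped >= 0))
  expect_equal(unname(k_clamped), unname(pmax(k_manual, 0)))
})

test_that("duplicated samples share diagonal and off-diagonal kinship", {
  dos <- rbind(a = c(0L, 2L, 1L, 2L), b = c(0L, 2L, 1L, 2L),
               c = c(2L, 0L, 1L, 0L))
  g <- make_panel(dos, pos = c(1L, 2L, 3L, 4L) * 100L)
  k <- vanraden_kinship(g, clamp_negative = FALSE)
  expect_equal(k["s001", "s002"], k["s001", "s001"])
})

test_that("standardized GRM has the exact zero-sum structure", {
  sim <- sim_genotypes(sim_config(n_per_subpop = c(25, 25), n_snps = 300,
                                  missing_rate = 0, seed = 51))
  qc <- qc_filter(sim$genotypes)
  a <- standardized_grm(qc$genotypes)
  # with sample-estimated frequencies each standardized column sums to zero,
  # so all entries of A sum to zero: mean offdiag = -mean(diag)/(n-1)
  n <- nrow(a)
  expect_lt(abs(sum(a)), 1e-8)
  off <- a[lower.tri(a)]
  expect_equal(mean(off), -mean(diag(a)) / (n - 1), tolerance = 1e-10)
})

test_that("GRM diagonal is ~1 for a panmictic non-inbred population", {
  sim <- sim_genotypes(sim_config(n_per_subpop = 200, n_snps = 1000,
                                  fst_drift = 1e-4, n_selected = 0,
                                  selfing_het = 0.98, missing_rate = 0,
                                  seed = 52))
  a <- standardized_grm(sim$genotypes)
  d <- diag(a)
  expect_lt(abs(mean(d) - 1), 3 * sd(d) / sqrt(length(d)) + 0.03)
})

test_that("two samples with opposite homozygotes give off-diagonal -2", {
  # p = 0.5, centered dosages -1 and +1, scaled by 2pq = 0.5:
  # A12 = (-1)(+1)/0.5 = -2 (and the zero-sum identity holds: diag is +2)
  g <- make_panel(rbind(c(0L), c(2L)))
  a <- standardized_grm(g)
  expect_equal(a[1, 2], -2)
  expect_equal(diag(a), c(s001 = 2, s002 = 2))
})

test_that("monomorphic variants are rejected by the standardized GRM", {
  g <- make_panel(rbind(c(0L, 0L), c(0L, 2L)), pos = c(1L, 100L))
  expect_error(standardized_grm(g), "polymorphic")
})

test_that("PCA returns descending eigenpairs with fixed sign convention", {
  u <- c(3, 1, -2, -1, -1) / sqrt(16)
  grm <- 5 * tcrossprod(u)
  res <- grm_pca(grm, k = 3)
  expect_equal(res$var_explained[1], 1, tolerance = 1e-12)
  expect_gt(res$vectors[which.max(abs(res$vectors[, 1])), 1], 0)
  expect_true(all(diff(res$values) <= 1e-12))

  ident <- diag(4)
  res_id <- grm_pca(ident, k = 4)
  expect_equal(res_id$var_explained, rep(0.25, 4))
  expect_warning(grm_pca(ident, k = 10), "reduced")
})

test_that("PC1 separates two simulated subpopulations", {
  sim <- sim_genotypes(sim_config(n_per_subpop = c(60, 60), n_snps = 2000,
                                  fst_drift = 0.05, n_selected = 0,
                                  seed = 53))
  qc <- qc_filter(sim$genotypes)
  res <- grm_pca(standardized_grm(qc$genotypes), k = 2)
  grp <- as.numeric(factor(subpops(qc$genotypes)))
  expect_gt(abs(cor(res$vectors[, 1], grp)), 0.9)
})

test_that("Rogers distance matches its closed form on small fixtures", {
  g_id <- make_panel(rbind(c(0L, 2L, 1L), c(0L, 2L, 1L)),
                     pos = c(1L, 2L, 3L) * 10L)
  expect_equal(rogers_distance(g_id)[1, 2], 0)
  g_opp <- make_panel(rbind(c(0L, 2L), c(2L, 0L)), pos = c(10L, 20L))
  expect_equal(rogers_distance(g_opp)[1, 2], 1)
  g_half <- make_panel(rbind(c(2L), c(1L)))      # AA vs AB at one locus
  expect_equal(rogers_distance(g_half)[1, 2], 0.5)
})

test_that("Rogers distance skips loci missing in either individual", {
  g <- make_panel(rbind(c(0L, NA, 2L), c(2L, 0L, NA)),
                  pos = c(1L, 2L, 3L) * 10L)
  # only locus 1 is shared: |0-2|/2 / 1 = 1
  expect_equal(rogers_distance(g)[1, 2], 1)
})

test_that("kinship and GRM are equivariant under sample permutation", {
  sim <- sim_genotypes(sim_config(n_per_subpop = c(10, 10), n_snps = 150,
                                  seed = 54))
  qc <- qc_filter(sim$genotypes)
  g <- qc$genotypes
  perm <- sample(n_samples(g))
  a1 <- standardized_grm(g)
  a2 <- standardized_grm(g[perm, ])
  expect_equal(unname(a2), unname(a1[perm, perm]))
})

test_that("neighbor joining is exact on an additive distance matrix", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> additive pairwise path lengths
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- nj_tree(d)
  path <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_lt(max(abs(path - d)), 1e-9)
  # AB cherry present
  pairs <- ape::prop.part(tr)
  expect_equal(sort(tr$tip.label), LETTERS[1:4])

  nwk <- tempfile(fileext = ".nwk")
  nj_tree(d, newick_path = nwk)
  expect_true(file.exists(nwk))
  expect_match(readLines(nwk), "^\\(")
})

test_that("three taxa resolve to the closed-form star tree", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  path <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_lt(max(abs(path - d)), 1e-9)
})

test_that("effective statistics follow their defining formulas", {
  grm <- diag(3)
  grm[lower.tri(grm)] <- grm[upper.tri(grm)] <- -0.0046
  es <- effective_stats(grm)
  expect_equal(es$n_e, 1 / 0.0046, tolerance = 1e-9)
  # sample-frequency GRM identity: g_bar = -1/(n-1) -> n_e = n - 1
  n <- 12
  grm2 <- diag(n)
  grm2[lower.tri(grm2)] <- grm2[upper.tri(grm2)] <- -1 / (n - 1)
  expect_equal(effective_stats(grm2)$n_e, n - 1)
})

test_that("single-population GRM gives n_e near n and large m_e", {
  sim <- sim_genotypes(sim_config(n_per_subpop = 100, n_snps = 3000,
                                  fst_drift = 1e-4, n_selected = 0,
                                  selfing_het = 0.99, missing_rate = 0,
                                  seed = 55))
  qc <- qc_filter(sim$genotypes)
  es <- effective_stats(standardized_grm(qc$genotypes))
  expect_gt(es$m_e, 10)
  expect_lt(abs(es$n_e - 100) / 100, 0.1)
})
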