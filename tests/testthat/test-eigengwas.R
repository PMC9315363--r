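test_that("the per-SNP scan equals the closed-form OLS oracle", {
  set.seed(81)
  n <- 20
  dos <- matrix(sample(c(0L, 1L, 2L, NA), n * 15, replace = TRUE,
                       prob = c(0.4, 0.15, 0.4, 0.05)), n, 15)
  keep <- apply(dos, 2, function(x) length(unique(na.omit(x))) > 1)
  g <- make_panel(dos[, keep, drop = FALSE],
                  pos = (seq_len(sum(keep))) * 1000L)
  pca <- grm_pca(diag(n) - 1 / n, k = 3)     # any orthonormal response set
  y <- pca$vectors[, 2]
  scan <- eigengwas_scan(g, pca, evs = 2)
  for (j in seq_len(n_variants(g))) {
    x <- g$dosages[, j]
    fit <- lm(y ~ x)
    sm <- summary(fit)$coefficients
    expect_equal(scan$beta[j], sm["x", "Estimate"], tolerance = 1e-10)
    expect_equal(scan$se[j], sm["x", "Std. Error"], tolerance = 1e-10)
    t2 <- sm["x", "t value"]^2
    expect_equal(scan$chi[j], t2, tolerance = 1e-9)
    expect_equal(scan$p_raw[j], pchisq(t2, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("orthogonal and collinear responses give the boundary statistics", {
  n <- 12
  x <- c(rep(0L, 6), rep(2L, 6))
  y_orth <- rep(c(-1, 1), 6) / sqrt(12)     # orthogonal to centered x
  g <- make_panel(cbind(x))
  fit <- eigensel:::ols_scan_one(g$dosages, y_orth)
  expect_equal(fit$beta, 0, tolerance = 1e-12)
  expect_equal(fit$chi, 0, tolerance = 1e-12)
  expect_equal(fit$p, 1)

  # response proportional to centered x: essentially perfect association
  set.seed(82)
  n2 <- 200
  x2 <- sample(c(0L, 2L), n2, replace = TRUE)
  y2 <- (x2 - mean(x2)) + rnorm(n2, sd = 1e-4)
  fit2 <- eigensel:::ols_scan_one(cbind(x2), y2)
  expect_gt(fit2$chi, 1e3)
})

test_that("lambda_GC follows its definition and null calibration", {
  expect_equal(lambda_gc(rep(qchisq(0.5, 1), 5)), 1)
  chi <- c(0.2, 0.5, 1, 2, 5)
  expect_equal(lambda_gc(2 * chi), 2 * lambda_gc(chi))
  set.seed(83)
  null_chi <- rchisq(1e5, df = 1)
  expect_lt(abs(lambda_gc(null_chi) - 1), 0.02)
})

test_that("genomic control adjusts p through the chi-square tail", {
  chi <- c(0, 1, 3.84)
  expect_equal(adjust_p(chi, 1), pchisq(chi, 1, lower.tail = FALSE))
  expect_equal(adjust_p(3.84, 2), pchisq(1.92, 1, lower.tail = FALSE))
  expect_equal(round(adjust_p(3.84, 2), 3), 0.166)
  expect_equal(adjust_p(0, 5), 1)
  # with lambda >= 1 adjustment can only weaken significance
  expect_true(all(adjust_p(chi, 1.7) >= pchisq(chi, 1, lower.tail = FALSE)))
})

test_that("significance selection applies the cutoff inclusively", {
  rec <- tibble::tibble(minus_log10_p_gc = c(5.01, 5.00, 4.99, NA))
  kept <- select_significant(rec, 5.0)
  expect_equal(kept$minus_log10_p_gc, c(5.01, 5.00))
})

test_that("region merging reproduces the 5 Mb flank bookkeeping", {
  one <- tibble::tibble(ev = 1L, chrom = "2D", pos = 16962948L,
                        name = "2D_16962948", minus_log10_p_gc = 6)
  reg <- merge_regions(one)$regions
  expect_equal(reg$start_mb, 11.96)
  expect_equal(reg$end_mb, 21.96)
  expect_equal(reg$top_snp, "2D_16962948")

  # overlapping windows merge transitively; distant SNP separate
  three <- tibble::tibble(
    ev = 1L, chrom = "1A", pos = c(12e6L, 14e6L, 30e6L),
    name = sprintf("1A_%d", c(12000000L, 14000000L, 30000000L)),
    minus_log10_p_gc = c(6, 7, 8)
  )
  reg3 <- merge_regions(three)$regions
  expect_equal(nrow(reg3), 2)
  expect_equal(reg3$n_snps, c(2, 1))
  expect_equal(reg3$top_snp[1], "1A_14000000")   # larger -log10 p wins

  # floor at zero
  low <- tibble::tibble(ev = 2L, chrom = "6A", pos = 3e6L, name = "6A_3000000",
                        minus_log10_p_gc = 5.5)
  regl <- merge_regions(low)$regions
  expect_equal(regl$start_mb, 0)
  expect_equal(regl$end_mb, 8)
})

test_that("regions stay separate across EVs but collapse in the unique count", {
  rec <- tibble::tibble(
    ev = c(1L, 2L), chrom = "3B", pos = c(20e6L, 22e6L),
    name = c("3B_20000000", "3B_22000000"), minus_log10_p_gc = c(6, 6)
  )
  out <- merge_regions(rec)
  expect_equal(nrow(out$regions), 2)      # one per EV
  expect_equal(out$n_unique_regions, 1L)  # overlapping intervals collapse
  fst_tab <- tibble::tibble(name = rec$name, theta = c(0.25, 0.4))
  out2 <- merge_regions(rec, per_snp_fst = fst_tab)
  expect_equal(out2$regions$fst, c(0.25, 0.4))
})

test_that("ties in the representative SNP break to the smaller position", {
  rec <- tibble::tibble(ev = 1L, chrom = "7B", pos = c(10e6L, 12e6L),
                        name = c("7B_10000000", "7B_12000000"),
                        minus_log10_p_gc = c(6, 6))
  reg <- merge_regions(rec)$regions
  expect_equal(reg$top_snp, "7B_10000000")
})

test_that("permutation thresholds are reproducible and grow with SNP count", {
  sim_small <- sim_genotypes(sim_config(n_per_subpop = 60, n_snps = 300,
                                        fst_drift = 0.01, n_selected = 0,
                                        missing_rate = 0, seed = 84))
  qs <- qc_filter(sim_small$genotypes)$genotypes
  pca <- grm_pca(standardized_grm(qs), k = 1)
  t1 <- permutation_threshold(qs, pca, ev = 1, n_perm = 120, seed = 9)
  t2 <- permutation_threshold(qs, pca, ev = 1, n_perm = 120, seed = 9)
  expect_identical(t1$threshold, t2$threshold)

  sim_big <- sim_genotypes(sim_config(n_per_subpop = 60, n_snps = 3000,
                                      fst_drift = 0.01, n_selected = 0,
                                      missing_rate = 0, seed = 85))
  qb <- qc_filter(sim_big$genotypes)$genotypes
  pcb <- grm_pca(standardized_grm(qb), k = 1)
  tb <- permutation_threshold(qb, pcb, ev = 1, n_perm = 120, seed = 9)
  expect_gt(tb$threshold, t1$threshold)   # more tests, more extreme minima
})

test_that("~5% of fresh null permutations exceed the permutation threshold", {
  sim <- sim_genotypes(sim_config(n_per_subpop = 50, n_snps = 250,
                                  fst_drift = 0.01, n_selected = 0,
                                  missing_rate = 0, seed = 86))
  g <- qc_filter(sim$genotypes)$genotypes
  pca <- grm_pca(standardized_grm(g), k = 1)
  thr <- permutation_threshold(g, pca, ev = 1, n_perm = 200, seed = 10)
  set.seed(11)
  y <- pca$vectors[, 1]
  fresh <- replicate(200, {
    fit <- eigensel:::ols_scan_one(g$dosages, sample(y))
    min(adjust_p(fit$chi, lambda_gc(fit$chi)), na.rm = TRUE)
  })
  frac <- mean(-log10(fresh) > thr$threshold)
  # binomial 3-sigma band around 0.05 at 200 draws
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200) + 0.01)
})

test_that("EigenGWAS -log10(P_GC) mirrors per-SNP FST on structured data", {
  sim <- sim_genotypes(sim_config(n_per_subpop = c(60, 60), n_snps = 2000,
                                  fst_drift = 0.05, n_selected = 20,
                                  selected_delta = 0.5, missing_rate = 0,
                                  seed = 87))
  g <- qc_filter(sim$genotypes)$genotypes
  pca <- grm_pca(standardized_grm(g), k = 1)
  scan <- eigengwas_scan(g, pca, evs = 1)
  fst <- wc_fst_per_snp(g)
  ok <- !is.na(scan$minus_log10_p_gc) & !is.na(fst$theta)
  rho <- cor(scan$minus_log10_p_gc[ok], fst$theta[ok], method = "spearman")
  expect_gt(rho, 0.6)
})

test_that("p_gc never understates p_raw when lambda exceeds one", {
  sim <- sim_genotypes(sim_config(n_per_subpop = c(30, 30), n_snps = 400,
                                  fst_drift = 0.05, seed = 88))
  g <- qc_filter(sim$genotypes)$genotypes
  scan <- eigengwas_scan(g, grm_pca(standardized_grm(g), k = 2), evs = 1:2)
  expect_true(all(scan$lambda_gc > 1))
  expect_true(all(scan$p_gc >= scan$p_raw, na.rm = TRUE))
  expect_true(all(scan$p_gc > 0 & scan$p_gc <= 1, na.rm = TRUE))
})
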