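#' Default pipeline configuration
#'
#' Returns the full list of pipeline settings, optionally overridden from a
#' YAML file and/or by `...` arguments. Paths (`vcf`, `metadata`) must be
#' set for [run_pipeline()]; everything else has the defaults used
#' throughout the package.
#'
#' @param path Optional YAML file with any subset of the settings.
#' @param ... Named overrides applied after the file.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    vcf = NULL, metadata = NULL, out_dir = "eigensel-out",
    max_missing = 0.50, min_maf = 0.05, max_het = 0.20,
    window = 1e6, step = 1e5,
    ld_max_distance = 5e7, ld_threshold = 0.1,
    n_evs = 10L, cutoff = 5.0, flank_bp = 5e6,
    n_perm_fst = 1000L, n_perm_threshold = 0L,
    seed = 1L
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) stop("unknown config field(s): ",
                              paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

write_tsv_commented <- function(x, path, comment = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full diversity / structure / selection-scan pipeline
#'
#' Executes, in order: VCF + metadata input, marker QC, per-marker
#' diversity and Ts/Tv summaries, sliding-window pi and Tajima's D,
#' kinship / GRM / PCA / Rogers distance / NJ tree, per-SNP and pairwise
#' F_ST and AMOVA, LD scan and decay fit, and the EigenGWAS selection scan
#' with region merging. Every stage writes a TSV (or Newick) file to
#' `out_dir`; a run manifest with the config, a config hash, and per-file
#' checksums is written last.
#'
#' @param config A [pipeline_config()] list with at least `vcf` and
#'   `metadata` set.
#' @return Invisibly, a list of the in-memory stage results (including
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (field in c("vcf", "metadata")) {
    if (is.null(config[[field]])) stop("config field not set: ", field)
    if (!file.exists(config[[field]])) {
      stop("config field ", field, ": file not found: ", config[[field]])
    }
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- function(name, expr) {
    message("[eigensel] stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  g_raw <- stage("input", read_vcf(config$vcf, config$metadata))
  qc <- stage("qc", qc_filter(g_raw, config$max_missing, config$min_maf,
                              config$max_het))
  g <- qc$genotypes
  write_tsv_commented(qc$report, file.path(out, "qc_report.tsv"),
                      "marker QC removal counts by first failing rule")

  ms <- stage("diversity", marker_stats(g, by_subpop = TRUE))
  write_tsv_commented(ms, file.path(out, "marker_stats.tsv"))
  write_tsv_commented(grouped_summary(g, "chromosome"),
                      file.path(out, "chromosome_summary.tsv"))
  write_tsv_commented(grouped_summary(g, "genome"),
                      file.path(out, "genome_summary.tsv"))
  subst <- substitution_summary(g)
  write_tsv_commented(subst$classes, file.path(out, "substitution_classes.tsv"),
                      sprintf("Ts %.2f%%, Tv %.2f%%, Ts/Tv %.2f",
                              subst$ts_pct, subst$tv_pct, subst$ts_tv_ratio))

  win <- stage("windows", windowed_stats(g, config$window, config$step,
                                         by_subpop = TRUE))
  write_tsv_commented(win, file.path(out, "windowed_pi_tajima.tsv"))

  grm <- stage("structure", standardized_grm(g))
  kin <- vanraden_kinship(g)
  pca <- grm_pca(grm, k = config$n_evs)
  rd <- rogers_distance(g)
  nj_tree(rd, newick_path = file.path(out, "nj_tree.nwk"))
  utils::write.table(round(kin, 6), file.path(out, "kinship.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(round(rd, 6), file.path(out, "rogers_distance.tsv"),
                     sep = "\t", quote = FALSE)
  write_tsv_commented(
    tibble::tibble(component = seq_along(pca$values),
                   eigenvalue = pca$values,
                   var_explained_pct = 100 * pca$var_explained),
    file.path(out, "pca_eigenvalues.tsv")
  )
  write_tsv_commented(
    dplyr::bind_cols(tibble::tibble(sample_id = rownames(pca$vectors),
                                    subpop = subpops(g)),
                     tibble::as_tibble(pca$vectors)),
    file.path(out, "pca_scores.tsv")
  )

  fst_snp <- stage("fst", wc_fst_per_snp(g))
  write_tsv_commented(fst_snp, file.path(out, "fst_per_snp.tsv"))
  fst_pairs <- pairwise_fst_matrix(g, n_perm = config$n_perm_fst)
  write_tsv_commented(fst_pairs, file.path(out, "fst_pairwise.tsv"))
  am <- amova(g, n_perm = config$n_perm_fst)
  write_tsv_commented(am$table, file.path(out, "amova.tsv"))

  ld <- stage("ld", ld_scan(g, config$ld_max_distance))
  ld_fit <- fit_ld_decay(ld, n_samples(g), config$ld_threshold)
  write_tsv_commented(ld, file.path(out, "ld_pairs.tsv"))
  write_tsv_commented(glance(ld_fit), file.path(out, "ld_decay_fit.tsv"))

  scan <- stage("eigengwas",
                eigengwas_scan(g, pca, evs = seq_len(config$n_evs)))
  write_tsv_commented(scan, file.path(out, "eigengwas_scan.tsv"))
  diag_tab <- scan |>
    dplyr::distinct(.data$ev, .data$lambda_gc) |>
    dplyr::mutate(eigenvalue = pca$values[.data$ev])
  write_tsv_commented(
    dplyr::bind_cols(diag_tab,
                     effective_stats(grm)[rep(1, nrow(diag_tab)), ]),
    file.path(out, "scan_diagnostics.tsv")
  )
  if (config$n_perm_threshold > 0) {
    thr <- permutation_threshold(g, pca, ev = 1,
                                 n_perm = config$n_perm_threshold,
                                 seed = config$seed)
    write_tsv_commented(
      tibble::tibble(threshold_minus_log10 = thr$threshold,
                     n_perm = thr$n_perm),
      file.path(out, "permutation_threshold.tsv")
    )
  }
  sig <- select_significant(scan, cutoff = config$cutoff)
  reg <- merge_regions(sig, flank_bp = config$flank_bp, per_snp_fst = fst_snp)
  write_tsv_commented(reg$regions, file.path(out, "selection_regions.tsv"),
                      sprintf("unique cross-EV regions: %d",
                              reg$n_unique_regions))

  manifest <- run_manifest(config, out)
  results <- list(qc = qc, marker_stats = ms, windows = win, grm = grm,
                  pca = pca, fst_per_snp = fst_snp, fst_pairwise = fst_pairs,
                  amova = am, ld_fit = ld_fit, scan = scan, regions = reg,
                  manifest = manifest)
  invisible(results)
}

run_manifest <- function(config, out_dir) {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  yaml::write_yaml(unclass(config), cfg_file)
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- tibble::tibble(
    file = c("(config)", files),
    md5 = c(unname(tools::md5sum(cfg_file)),
            unname(tools::md5sum(file.path(out_dir, files))))
  )
  write_tsv_commented(
    manifest, file.path(out_dir, "manifest.tsv"),
    sprintf("eigensel %s | seed %d | %s",
            as.character(utils::packageVersion("eigensel")),
            config$seed, format(Sys.time(), "%Y-%m-%d"))
  )
  manifest
}
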