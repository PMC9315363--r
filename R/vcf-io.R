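#' Write a genotype panel to a VCF 4.2 file
#'
#' Plain-text, deterministic writer: one record per variant with GT-only
#' sample columns (`0/0`, `0/1`, `1/1`, `./.`), CHROM/POS/REF/ALT taken from
#' the variant table, ID set to the `chrom_pos` marker name, and samples in
#' panel order. The output round-trips losslessly through [read_vcf()], and
#' identical panels yield byte-identical files.
#'
#' @param g A [genotypes] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotypes"))
  if (n_variants(g) == 0 || n_samples(g) == 0) stop("empty genotype panel")
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  dos <- t(g$dosages)                       # variants x samples
  gt <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_code[as.character(dos[ok])]
  body <- paste(
    g$variants$chrom, g$variants$pos, g$variants$name,
    g$variants$ref, g$variants$alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  contigs <- unique(g$variants$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", contigs),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples$sample_id), collapse = "\t")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write the sample-metadata table alongside a VCF
#'
#' @param g A [genotypes] object.
#' @param path Output TSV path (columns `sample_id`, `subpop`).
#' @return `path`, invisibly.
#' @export
write_metadata <- function(g, path) {
  utils::write.table(g$samples[, c("sample_id", "subpop")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a multi-sample VCF plus sample metadata into a genotype panel
#'
#' Keeps biallelic SNP records only (multiallelic and indel records are
#' dropped with a message). GT fields are converted to ALT-allele dosage;
#' half-calls and non-diploid genotypes become missing. Samples are
#' restricted to those present in both the VCF and the metadata table.
#'
#' @param path VCF file (plain or gzipped).
#' @param metadata_path Optional TSV with header `sample_id`, `subpop`;
#'   if `NULL`, all samples are labelled `"UNASSIGNED"`.
#' @return A [genotypes] object.
#' @export
read_vcf <- function(path, metadata_path = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)    # single-record VCF
  fix <- tibble::as_tibble(as.data.frame(fixm, stringsAsFactors = FALSE))
  n_in <- nrow(fix)
  snp <- fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T") &
    !is.na(fix$ALT)
  if (any(!snp)) {
    message("dropping ", sum(!snp), " non-biallelic-SNP record(s) of ", n_in)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  if (nrow(fix) == 0) stop("no biallelic SNP records in ", path)

  # GT string -> dosage; any half-call / non-diploid / missing -> NA
  dosage_of <- function(s) {
    s <- gsub("|", "/", s, fixed = TRUE)
    d <- rep(NA_integer_, length(s))
    d[s == "0/0"] <- 0L
    d[s %in% c("0/1", "1/0")] <- 1L
    d[s == "1/1"] <- 2L
    d
  }
  dos <- matrix(dosage_of(as.vector(gt)), nrow(gt), ncol(gt))
  dos <- t(dos)                            # samples x variants

  vcf_samples <- colnames(gt)
  if (is.null(metadata_path)) {
    meta <- tibble::tibble(sample_id = vcf_samples, subpop = "UNASSIGNED")
  } else {
    meta <- tibble::as_tibble(utils::read.delim(metadata_path,
                                                colClasses = "character"))
    if (!all(c("sample_id", "subpop") %in% names(meta))) {
      stop("metadata must have columns sample_id and subpop")
    }
  }
  shared <- intersect(vcf_samples, meta$sample_id)
  if (length(shared) == 0) stop("no samples shared between VCF and metadata")
  meta <- meta[match(shared, meta$sample_id), c("sample_id", "subpop")]
  dos <- dos[match(shared, vcf_samples), , drop = FALSE]

  genotypes(
    dosages = dos,
    variants = tibble::tibble(
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT
    ),
    samples = meta
  )
}

#' Marker quality control
#'
#' Retains variants passing, in order: missing-call fraction `<= max_missing`;
#' mapped to one of the 21 wheat chromosomes (`1A`..`7D`); minor allele
#' frequency strictly `> min_maf`; observed heterozygosity strictly
#' `< max_het`. MAF and heterozygosity are computed on non-missing calls.
#' Each removed variant is attributed to the first rule it fails.
#'
#' @param g A [genotypes] object.
#' @param max_missing Maximum missing fraction (default 0.50).
#' @param min_maf MAF must exceed this (default 0.05).
#' @param max_het Observed heterozygosity must be below this (default 0.20).
#' @return A list with `genotypes` (filtered panel) and `report`, a tibble of
#'   per-rule removal counts plus the retained total (removed + retained
#'   equals the input count).
#' @export
#' @examples
#' sim <- sim_genotypes(sim_config(n_per_subpop = c(20, 20), n_snps = 100,
#'                                 seed = 7))
#' qc <- qc_filter(sim$genotypes)
#' qc$report
qc_filter <- function(g, max_missing = 0.50, min_maf = 0.05, max_het = 0.20) {
  stopifnot(inherits(g, "genotypes"),
            max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 1, max_het >= 0, max_het <= 1)
  dos <- g$dosages
  n <- nrow(dos)
  miss <- colMeans(is.na(dos))
  n_called <- colSums(!is.na(dos))
  p <- ifelse(n_called > 0, colSums(dos, na.rm = TRUE) / (2 * n_called), NA)
  maf <- pmin(p, 1 - p)
  het <- ifelse(n_called > 0,
                colSums(dos == 1L, na.rm = TRUE) / n_called, NA)
  mapped <- genome_of(g$variants$chrom) != "UNMAPPED"

  fail_missing <- miss > max_missing
  fail_unmapped <- !fail_missing & !mapped
  fail_maf <- !fail_missing & !fail_unmapped & (is.na(maf) | maf <= min_maf)
  fail_het <- !fail_missing & !fail_unmapped & !fail_maf &
    (is.na(het) | het >= max_het)
  keep <- !(fail_missing | fail_unmapped | fail_maf | fail_het)

  report <- tibble::tibble(
    rule = c("missingness", "unmapped", "maf", "heterozygosity", "retained"),
    n = c(sum(fail_missing), sum(fail_unmapped), sum(fail_maf),
          sum(fail_het), sum(keep))
  )
  if (!any(keep)) warning("no variants pass QC")
  list(genotypes = g[, keep], report = report)
}
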