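#' Genotype panel: dosage matrix plus variant and sample tables
#'
#' The backbone object of the package. It bundles a samples x variants
#' dosage matrix (counts of the ALT allele: 0, 1, 2, or `NA` for a missing
#' call) with a variant table (chromosome, position, REF/ALT alleles and the
#' derived `chrom_pos` marker name) and a sample table (sample ID and
#' subpopulation label). Variants are kept sorted by chromosome then
#' position; marker names follow the `chrom_pos` convention, e.g.
#' `1A_555961328`.
#'
#' @param dosages Integer/numeric matrix, samples in rows, variants in
#'   columns, values in `{0, 1, 2, NA}`. Row names are sample IDs; column
#'   names, if present, are ignored and rebuilt from `variants`.
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (one row per matrix column). A `name` column is derived as
#'   `chrom_pos` if absent.
#' @param samples Data frame with columns `sample_id` and `subpop` (one row
#'   per matrix row). Missing labels become `"UNASSIGNED"`.
#'
#' @return An object of class `genotypes`: a list with elements `dosages`
#'   (matrix), `variants` (tibble), `samples` (tibble).
#' @export
#' @examples
#' g <- genotypes(
#'   dosages  = rbind(s1 = c(0, 1), s2 = c(2, NA)),
#'   variants = data.frame(chrom = c("1A", "2B"), pos = c(100L, 500L),
#'                         ref = c("A", "C"), alt = c("G", "T")),
#'   samples  = data.frame(sample_id = c("s1", "s2"),
#'                         subpop = c("POP1", "POP2"))
#' )
#' g
genotypes <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)

  stopifnot(
    nrow(variants) == ncol(dosages),
    nrow(samples) == nrow(dosages),
    all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
    "sample_id" %in% names(samples)
  )
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  variants$name <- paste0(variants$chrom, "_", variants$pos)

  if (!"subpop" %in% names(samples)) samples$subpop <- "UNASSIGNED"
  samples$subpop[is.na(samples$subpop)] <- "UNASSIGNED"
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample IDs")

  bad <- !(dosages %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")

  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- variants$name

  structure(
    list(dosages = dosages, variants = variants, samples = samples),
    class = "genotypes"
  )
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf(
    "<genotypes> %d samples x %d variants (%.2f%% missing)\n",
    nrow(x$dosages), ncol(x$dosages),
    100 * mean(is.na(x$dosages))
  ))
  tab <- table(x$samples$subpop)
  cat("subpopulations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  cat("chromosomes:", paste(unique(x$variants$chrom), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$dosages)

#' Number of samples / variants in a genotype panel
#' @param g A [genotypes] object.
#' @return Integer scalar.
#' @export
n_samples <- function(g) nrow(g$dosages)

#' @rdname n_samples
#' @export
n_variants <- function(g) ncol(g$dosages)

#' Subset a genotype panel
#'
#' @param x A [genotypes] object.
#' @param i Sample index (logical, integer, or sample IDs).
#' @param j Variant index (logical, integer, or marker names).
#' @param ... Unused.
#' @return A [genotypes] object.
#' @export
`[.genotypes` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$variants$name)
  genotypes(
    dosages = x$dosages[i, j, drop = FALSE],
    variants = x$variants[j, , drop = FALSE],
    samples = x$samples[i, , drop = FALSE]
  )
}

#' Subpopulation labels in sample order
#' @param g A [genotypes] object.
#' @return Character vector, one label per sample.
#' @export
subpops <- function(g) g$samples$subpop

#' Map a chromosome name to its genome label
#'
#' Hexaploid wheat chromosomes are named `1A`..`7D`; the trailing letter is
#' the subgenome. Anything else (scaffolds, `"Un"`) is `"UNMAPPED"`.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector of `"A"`, `"B"`, `"D"` or `"UNMAPPED"`.
#' @export
#' @examples
#' genome_of(c("2B", "7D", "Un"))
genome_of <- function(chrom) {
  ifelse(grepl("^[1-7][ABD]$", chrom), sub("^[1-7]", "", chrom), "UNMAPPED")
}

#' Per-variant ALT-allele frequency
#'
#' Computed over non-missing calls: `p = sum(dosage) / (2 * n_called)`.
#' Variants with no called genotype get `NA` (with a warning).
#'
#' @param g A [genotypes] object, or a dosage matrix/vector.
#' @return Numeric vector of ALT-allele frequencies, one per variant.
#' @export
allele_frequency <- function(g) {
  x <- if (inherits(g, "genotypes")) g$dosages else g
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n_called <- colSums(!is.na(x))
  p <- colSums(x, na.rm = TRUE) / (2 * n_called)
  if (any(n_called == 0)) {
    warning(sum(n_called == 0), " variant(s) with no called genotypes")
    p[n_called == 0] <- NA_real_
  }
  unname(p)
}
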