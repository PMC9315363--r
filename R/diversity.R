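#' Polymorphism information content of a biallelic locus
#'
#' Botstein's PIC restricted to two alleles:
#' `PIC = 1 - p^2 - q^2 - 2 p^2 q^2` with `q = 1 - p`. Maximal at
#' `p = 0.5` (0.375); 0 at a monomorphic locus.
#'
#' @param p Allele frequency (vectorised), in \[0, 1\].
#' @return Numeric vector of PIC values.
#' @export
#' @examples
#' pic(c(0.5, 0.05, 0))
pic <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- 1 - p
  1 - p^2 - q^2 - 2 * p^2 * q^2
}

#' Nei gene diversity (expected heterozygosity) of a biallelic locus
#'
#' `GD = 1 - p^2 - q^2 = 2pq`; maximal 0.5 at `p = 0.5`.
#'
#' @inheritParams pic
#' @return Numeric vector of gene-diversity values.
#' @export
gene_diversity <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  1 - p^2 - (1 - p)^2
}

#' Per-marker diversity statistics
#'
#' ALT-allele frequency, MAF, observed heterozygosity (heterozygote fraction
#' among non-missing calls), Nei gene diversity, and PIC for every variant.
#' Frequencies use non-missing calls only.
#'
#' @param g A [genotypes] object.
#' @param by_subpop If `TRUE`, statistics are recomputed within each
#'   subpopulation (stacked long with a `group` column) in addition to the
#'   whole-panel rows (`group = "WP"`).
#' @return Tibble with columns `group`, `name`, `chrom`, `pos`, `p`, `maf`,
#'   `he_obs`, `gd`, `pic`, `n_called`.
#' @export
marker_stats <- function(g, by_subpop = FALSE) {
  stopifnot(inherits(g, "genotypes"))
  one <- function(sub, label) {
    dos <- sub$dosages
    n_called <- colSums(!is.na(dos))
    p <- ifelse(n_called > 0, colSums(dos, na.rm = TRUE) / (2 * n_called), NA)
    tibble::tibble(
      group = label,
      name = sub$variants$name, chrom = sub$variants$chrom,
      pos = sub$variants$pos,
      p = p, maf = pmin(p, 1 - p),
      he_obs = ifelse(n_called > 0,
                      colSums(dos == 1L, na.rm = TRUE) / n_called, NA),
      gd = gene_diversity(p), pic = pic(p),
      n_called = n_called
    )
  }
  out <- one(g, "WP")
  if (by_subpop) {
    for (sp in sort(unique(subpops(g)))) {
      out <- dplyr::bind_rows(out, one(g[subpops(g) == sp, ], sp))
    }
  }
  out
}

#' Classify a SNP substitution
#'
#' Maps an unordered REF/ALT base pair to one of the six substitution
#' classes `A/G`, `C/T` (transitions) and `A/T`, `A/C`, `G/T`, `C/G`
#' (transversions). Classes are kept distinct (no strand collapsing:
#' `G/T` is not folded into `A/C`).
#'
#' @param ref,alt Character vectors of single bases in `{A, C, G, T}`.
#' @return Character vector of class labels.
#' @export
#' @examples
#' classify_substitution(c("C", "T", "G"), c("T", "A", "T"))
classify_substitution <- function(ref, alt) {
  valid <- c("A", "C", "G", "T")
  if (!all(ref %in% valid) || !all(alt %in% valid)) {
    stop("ref/alt must be single bases A, C, G or T")
  }
  classes <- c("A/G", "C/T", "A/T", "A/C", "G/T", "C/G")
  key <- paste(pmin(ref, alt), pmax(ref, alt), sep = "/")
  out <- classes[match(key, classes)]
  if (anyNA(out)) stop("ref and alt must differ")
  out
}

#' Transition/transversion summary
#'
#' Counts and relative frequencies of the six substitution classes, the
#' transition and transversion totals, and the Ts/Tv ratio.
#'
#' @param variants A [genotypes] object, a variant tibble with `ref`/`alt`
#'   columns, or a named numeric vector of pre-tabulated class counts
#'   (names `A/G`, `C/T`, `A/T`, `A/C`, `G/T`, `C/G`).
#' @return A list with `classes` (tibble: class, type, n, pct),
#'   `ts_pct`, `tv_pct`, and `ts_tv_ratio` (`NA` with a warning when there
#'   are no transversions).
#' @export
substitution_summary <- function(variants) {
  classes <- c("A/G", "C/T", "A/T", "A/C", "G/T", "C/G")
  if (inherits(variants, "genotypes")) variants <- variants$variants
  if (is.numeric(variants)) {
    stopifnot(all(classes %in% names(variants)))
    counts <- variants[classes]
  } else {
    if (nrow(variants) == 0) stop("no variants")
    cls <- classify_substitution(variants$ref, variants$alt)
    counts <- table(factor(cls, levels = classes))
  }
  counts <- as.numeric(counts)
  total <- sum(counts)
  ts <- sum(counts[1:2])
  tv <- sum(counts[3:6])
  ratio <- if (tv == 0) {
    warning("no transversions: Ts/Tv ratio undefined")
    NA_real_
  } else ts / tv
  list(
    classes = tibble::tibble(
      class = classes,
      type = c("transition", "transition", rep("transversion", 4)),
      n = counts, pct = 100 * counts / total
    ),
    ts_pct = 100 * ts / total,
    tv_pct = 100 * tv / total,
    ts_tv_ratio = ratio
  )
}

#' Chromosome / genome / subpopulation summaries of a marker panel
#'
#' For `by = "chromosome"`: per chromosome, marker count, percentage of the
#' panel, min/max position, length in Mb (max observed position / 1e6),
#' marker density (markers per Mb of that length), and mean MAF/He/GD/PIC.
#' Genome rows (`by = "genome"`) and the whole-genome row report summed
#' counts and lengths, but their density is the unweighted mean of the
#' member chromosomes' densities. (Summary tables of this type often label
#' the density column "Mb/marker" although the values are markers per Mb;
#' here the value is always markers per Mb.) `by = "subpopulation"` returns
#' per-group means of the marker statistics.
#'
#' @param g A [genotypes] object.
#' @param by One of `"chromosome"`, `"genome"`, `"subpopulation"`.
#' @return A tibble, one row per group (plus a `TOTAL` row for chromosome
#'   and genome summaries).
#' @export
grouped_summary <- function(g, by = c("chromosome", "genome", "subpopulation")) {
  by <- match.arg(by)
  stopifnot(inherits(g, "genotypes"), n_variants(g) > 0)
  if (by == "subpopulation") {
    ms <- marker_stats(g, by_subpop = TRUE)
    return(
      ms |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(
          n_markers = dplyr::n(),
          maf = mean(.data$maf, na.rm = TRUE),
          he_obs = mean(.data$he_obs, na.rm = TRUE),
          gd = mean(.data$gd, na.rm = TRUE),
          pic = mean(.data$pic, na.rm = TRUE),
          .groups = "drop"
        )
    )
  }
  ms <- marker_stats(g)
  total <- nrow(ms)
  per_chrom <- ms |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      pct = 100 * dplyr::n() / total,
      start_pos = min(.data$pos), end_pos = max(.data$pos),
      length_mb = max(.data$pos) / 1e6,
      density = dplyr::n() / (max(.data$pos) / 1e6),
      maf = mean(.data$maf, na.rm = TRUE),
      he_obs = mean(.data$he_obs, na.rm = TRUE),
      gd = mean(.data$gd, na.rm = TRUE),
      pic = mean(.data$pic, na.rm = TRUE),
      .groups = "drop"
    )
  roll_up <- function(tab, label) {
    tibble::tibble(
      chrom = label,
      n_markers = sum(tab$n_markers),
      pct = sum(tab$pct),
      start_pos = min(tab$start_pos), end_pos = max(tab$end_pos),
      length_mb = sum(tab$length_mb),
      density = mean(tab$density),          # unweighted mean over chromosomes
      maf = stats::weighted.mean(tab$maf, tab$n_markers),
      he_obs = stats::weighted.mean(tab$he_obs, tab$n_markers),
      gd = stats::weighted.mean(tab$gd, tab$n_markers),
      pic = stats::weighted.mean(tab$pic, tab$n_markers)
    )
  }
  if (by == "chromosome") {
    return(dplyr::bind_rows(per_chrom, roll_up(per_chrom, "TOTAL")))
  }
  gen <- genome_of(per_chrom$chrom)
  rows <- lapply(unique(gen), function(gl) {
    roll_up(per_chrom[gen == gl, , drop = FALSE], gl)
  })
  dplyr::bind_rows(dplyr::bind_rows(rows), roll_up(per_chrom, "TOTAL"))
}
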