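#' Squared genotype correlation between two SNPs
#'
#' Composite (dosage-scale) linkage disequilibrium: the square of the
#' Pearson correlation between the two dosage vectors over their shared
#' non-missing samples. Undefined (`NA`) when fewer than 2 shared calls or
#' either SNP is monomorphic on the shared samples.
#'
#' @param x,y Dosage vectors of equal length.
#' @return Scalar r-squared in \[0, 1\] or `NA`.
#' @export
pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Intra-chromosomal LD scan
#'
#' All pairs of SNPs on the same chromosome separated by at most
#' `max_distance_bp`, with their dosage r-squared, per subpopulation and/or
#' for the whole panel. Ordering is deterministic: chromosome, then the two
#' positions ascending.
#'
#' @param g A [genotypes] object.
#' @param max_distance_bp Maximum pair distance in bp (default 50 Mb).
#' @param by_subpop Also scan within each subpopulation.
#' @return Tibble with `group`, `chrom`, `pos1`, `pos2`, `dist_bp`, `r2`
#'   (`NA` r2 rows from monomorphic-on-shared-samples pairs are dropped).
#' @export
ld_scan <- function(g, max_distance_bp = 5e7, by_subpop = FALSE) {
  stopifnot(inherits(g, "genotypes"), max_distance_bp > 0)
  scan_one <- function(sub, label) {
    v <- sub$variants
    out <- list()
    for (ch in unique(v$chrom)) {
      sel <- which(v$chrom == ch)
      if (length(sel) < 2) next
      pos <- v$pos[sel]
      dos <- sub$dosages[, sel, drop = FALSE]
      # correlation over complete cases per pair, vectorised via cor()
      r <- suppressWarnings(stats::cor(dos, use = "pairwise.complete.obs"))
      ij <- which(upper.tri(r), arr.ind = TRUE)
      d <- pos[ij[, 2]] - pos[ij[, 1]]
      keep <- d > 0 & d <= max_distance_bp
      ij <- ij[keep, , drop = FALSE]
      if (nrow(ij) == 0) next
      out[[ch]] <- tibble::tibble(
        group = label, chrom = ch,
        pos1 = pos[ij[, 1]], pos2 = pos[ij[, 2]],
        dist_bp = pos[ij[, 2]] - pos[ij[, 1]],
        r2 = r[ij]^2
      )
    }
    res <- dplyr::bind_rows(out)
    if (nrow(res) == 0) {
      return(tibble::tibble(group = character(), chrom = character(),
                            pos1 = integer(), pos2 = integer(),
                            dist_bp = integer(), r2 = numeric()))
    }
    res |>
      dplyr::arrange(.data$chrom, .data$pos1, .data$pos2) |>
      dplyr::filter(!is.na(.data$r2))
  }
  res <- scan_one(g, "WP")
  if (by_subpop) {
    for (sp in sort(unique(subpops(g)))) {
      res <- dplyr::bind_rows(res, scan_one(g[subpops(g) == sp, ], sp))
    }
  }
  res
}

#' Hill-Weir expected r-squared at distance d
#'
#' Remington's drift-plus-sampling parameterisation of the Hill & Weir
#' expectation with `C = beta * d`:
#' `E[r2] = (10+C)/((2+C)(11+C)) * (1 + ((3+C)(12+12C+C^2))/(n(2+C)(11+C)))`.
#' Monotonically decreasing in `d` for `beta > 0`, `n >= 4`.
#'
#' @param d Distance in bp (vectorised).
#' @param beta Per-bp decay coefficient (> 0).
#' @param n Sample size (number of individuals).
#' @return Expected r-squared values.
#' @export
hill_weir_r2 <- function(d, beta, n) {
  c_ <- beta * d
  (10 + c_) / ((2 + c_) * (11 + c_)) *
    (1 + ((3 + c_) * (12 + 12 * c_ + c_^2)) / (n * (2 + c_) * (11 + c_)))
}

#' Fit the Hill-Weir LD-decay curve and find the decay distance
#'
#' Nonlinear least squares (Levenberg-Marquardt) of observed `(distance,
#' r2)` pairs against [hill_weir_r2()], with the starting value chosen so
#' that `C = 1` at the median distance. The decay distance is the `d` at
#' which the fitted curve crosses `threshold`, found by bisection on the
#' monotone fitted curve; flagged `"not reached"` when the curve stays on
#' one side of the threshold over 10x the observed distance range.
#'
#' @param pairs Tibble from [ld_scan()] (needs `dist_bp`, `r2`), >= 50 rows.
#' @param n_samples Number of individuals behind the r2 values.
#' @param threshold r-squared level defining the decay distance
#'   (default 0.1).
#' @return Object of class `ld_decay_fit`: list with `beta`, `n`,
#'   `threshold`, `decay_bp` (NA if not reached), `decay_mb`, `reached`,
#'   `n_pairs`, and the `fit` object.
#' @export
fit_ld_decay <- function(pairs, n_samples, threshold = 0.1) {
  stopifnot(nrow(pairs) >= 50, n_samples >= 4)
  dat <- data.frame(d = as.numeric(pairs$dist_bp), r2 = pairs$r2)
  beta0 <- 1 / stats::median(dat$d)
  fit <- minpack.lm::nlsLM(
    r2 ~ hill_weir_r2(d, beta, n_samples),
    data = dat, start = list(beta = beta0),
    lower = 1e-12, control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  beta <- unname(stats::coef(fit)[["beta"]])
  d_max <- 10 * max(dat$d)
  f <- function(d) hill_weir_r2(d, beta, n_samples) - threshold
  if (f(0) <= 0 || f(d_max) >= 0) {
    decay <- NA_real_
    reached <- FALSE
  } else {
    decay <- stats::uniroot(f, c(0, d_max), tol = 1)$root
    reached <- TRUE
  }
  structure(
    list(beta = beta, n = n_samples, threshold = threshold,
         decay_bp = decay, decay_mb = decay / 1e6, reached = reached,
         n_pairs = nrow(dat), fit = fit),
    class = "ld_decay_fit"
  )
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("<ld_decay_fit> beta = %.3e /bp over %d pairs (n = %d)\n",
              x$beta, x$n_pairs, x$n))
  if (x$reached) {
    cat(sprintf("LD decays to r2 = %.2f at %.2f Mb\n", x$threshold, x$decay_mb))
  } else {
    cat(sprintf("fitted curve does not cross r2 = %.2f (not reached)\n",
                x$threshold))
  }
  invisible(x)
}
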