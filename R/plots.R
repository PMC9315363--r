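# shared helper: cumulative genome coordinates for Manhattan-style panels
genome_coords <- function(chrom, pos) {
  chroms <- sort(unique(chrom))
  max_pos <- tapply(pos, chrom, max)[chroms]
  offset <- c(0, cumsum(as.numeric(max_pos)))[seq_along(chroms)]
  names(offset) <- chroms
  list(x = pos + offset[chrom], offsets = offset, chroms = chroms,
       centers = offset + as.numeric(max_pos) / 2)
}

#' Miami plot: EigenGWAS significance above, per-SNP F_ST below
#'
#' The upper track shows `-log10(p_gc)` for one eigenvector; the lower
#' (negated) track shows the per-SNP Weir-Cockerham F_ST, so selection
#' peaks that agree between the two statistics mirror each other.
#'
#' @param scan Tibble from [eigengwas_scan()].
#' @param per_snp_fst Tibble from [wc_fst_per_snp()].
#' @param ev Eigenvector to display (default 1).
#' @param cutoff Significance line on the upper track (default 5).
#' @return A ggplot object.
#' @export
plot_miami <- function(scan, per_snp_fst, ev = 1, cutoff = 5.0) {
  up <- dplyr::filter(scan, .data$ev == !!ev)
  co <- genome_coords(up$chrom, up$pos)
  up$x <- co$x
  lo <- per_snp_fst
  lo$x <- genome_coords(lo$chrom, lo$pos)$x
  scale_dn <- max(up$minus_log10_p_gc, na.rm = TRUE) /
    max(lo$theta, na.rm = TRUE)
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = up,
      ggplot2::aes(.data$x, .data$minus_log10_p_gc, colour = .data$chrom),
      size = 0.5, show.legend = FALSE
    ) +
    ggplot2::geom_point(
      data = lo,
      ggplot2::aes(.data$x, -.data$theta * scale_dn, colour = .data$chrom),
      size = 0.5, show.legend = FALSE
    ) +
    ggplot2::geom_hline(yintercept = c(0, cutoff), linetype = c(1, 2)) +
    ggplot2::scale_x_continuous(breaks = co$centers, labels = co$chroms) +
    ggplot2::labs(
      x = NULL,
      y = expression(-log[10](P[GC]) ~ "(up) /" ~ F[ST] ~ "(down)"),
      title = sprintf("EigenGWAS EV%d", ev)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
}

#' LD-decay curve plot
#'
#' Observed pairwise r-squared against distance with the fitted Hill-Weir
#' expectation and the decay-distance threshold.
#'
#' @param object An `ld_decay_fit` from [fit_ld_decay()].
#' @param pairs The pair tibble the fit was made from (for the points);
#'   omitted if `NULL`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ld_decay_fit <- function(object, pairs = NULL, ...) {
  d_max <- if (!is.null(pairs)) max(pairs$dist_bp) else
    5 * (object$decay_bp %||% 1e7)
  curve <- tibble::tibble(
    d = seq(1, d_max, length.out = 400),
    r2 = hill_weir_r2(seq(1, d_max, length.out = 400), object$beta, object$n)
  )
  p <- ggplot2::ggplot()
  if (!is.null(pairs)) {
    p <- p + ggplot2::geom_point(
      data = pairs, ggplot2::aes(.data$dist_bp / 1e6, .data$r2),
      alpha = 0.15, size = 0.4
    )
  }
  p +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(.data$d / 1e6, .data$r2),
                       colour = "red") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    {
      if (object$reached) {
        ggplot2::geom_vline(xintercept = object$decay_mb, linetype = 2)
      }
    } +
    ggplot2::labs(x = "distance (Mb)", y = expression(r^2)) +
    ggplot2::theme_minimal()
}

#' PCA scatter of a genotype panel
#'
#' @param object A `grm_pca` from [grm_pca()].
#' @param groups Optional vector of subpopulation labels per sample.
#' @param components Two component indices (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grm_pca <- function(object, groups = NULL, components = c(1, 2),
                             ...) {
  dat <- tibble::tibble(
    x = object$vectors[, components[1]],
    y = object$vectors[, components[2]],
    group = if (is.null(groups)) "panel" else groups
  )
  pct <- 100 * object$var_explained[components]
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y, colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC%d (%.2f%%)", components[1], pct[1]),
      y = sprintf("PC%d (%.2f%%)", components[2], pct[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Windowed diversity track plot
#'
#' Per-chromosome lines of windowed nucleotide diversity or Tajima's D.
#'
#' @param windows Tibble from [windowed_stats()].
#' @param stat `"pi"` or `"tajima_d"`.
#' @param group Which group track to plot (default `"WP"`).
#' @return A ggplot object.
#' @export
plot_windows <- function(windows, stat = c("pi", "tajima_d"), group = "WP") {
  stat <- match.arg(stat)
  dat <- dplyr::filter(windows, .data$group == !!group)
  ggplot2::ggplot(dat,
                  ggplot2::aes((.data$start + .data$end) / 2e6,
                               .data[[stat]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = stat) +
    ggplot2::theme_minimal()
}
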