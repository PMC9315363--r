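#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL

#' Tidy an LD-decay fit
#'
#' @param x An `ld_decay_fit` object.
#' @param ... Unused.
#' @return One-row tibble with the fitted coefficient and its standard
#'   error.
#' @export
tidy.ld_decay_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = "beta",
    estimate = x$beta,
    std.error = sm["beta", "Std. Error"]
  )
}

#' @rdname tidy.ld_decay_fit
#' @return For `glance()`: one-row tibble with `beta`, `n`, `n_pairs`,
#'   `threshold`, `decay_mb`, `reached`.
#' @export
glance.ld_decay_fit <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, n = x$n, n_pairs = x$n_pairs,
    threshold = x$threshold, decay_mb = x$decay_mb, reached = x$reached
  )
}

#' Tidy a GRM eigendecomposition
#'
#' @param x A `grm_pca` object.
#' @param ... Unused.
#' @return Long tibble of sample scores: `sample_id`, `component`, `score`.
#' @export
tidy.grm_pca <- function(x, ...) {
  tibble::as_tibble(x$vectors, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "component",
                        values_to = "score") |>
    dplyr::mutate(component = as.integer(sub("^EV", "", .data$component)))
}

#' @rdname tidy.grm_pca
#' @return For `glance()`: tibble of eigenvalues and variance fractions.
#' @export
glance.grm_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$values),
    eigenvalue = x$values,
    var_explained = x$var_explained
  )
}

#' Tidy an AMOVA result
#'
#' @param x An `amova` object.
#' @param ... Unused.
#' @return The three-row AMOVA table as a tibble.
#' @export
tidy.amova <- function(x, ...) x$table

#' @rdname tidy.amova
#' @return For `glance()`: the totals row.
#' @export
glance.amova <- function(x, ...) x$totals
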