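#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a logistic fit
#' @param x a `cyto_logit`.
#' @param ... unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.cyto_logit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' One-row summary of a logistic fit
#' @param x a `cyto_logit`.
#' @param ... unused.
#' @return Tibble with `n`, `loglik`, `iterations`, `converged`,
#'   `separated`.
#' @export
glance.cyto_logit <- function(x, ...) {
  tibble::tibble(n = x$n, loglik = x$loglik, iterations = x$iterations,
                 converged = x$converged, separated = x$separated)
}

#' Tidy a marker-effects table
#' @param x a `marker_effects`.
#' @param ... unused.
#' @return Tibble with `term`, `estimate`, `conf.low`, `conf.high`,
#'   `significant`, `direction`.
#' @export
tidy.marker_effects <- function(x, ...) {
  tibble::tibble(term = x$marker, estimate = x$estimate,
                 conf.low = x$ci_low, conf.high = x$ci_high,
                 significant = x$significant, direction = x$direction)
}

#' One-row summary of a marker-effects table
#' @param x a `marker_effects`.
#' @param ... unused.
#' @return Tibble with the contrast, resample counts and cell counts.
#' @export
glance.marker_effects <- function(x, ...) {
  ctr <- attr(x, "contrast")
  tibble::tibble(reference = ctr[1], comparison = ctr[2],
                 n_markers = nrow(x),
                 n_significant = sum(x$significant),
                 n_boot = attr(x, "n_boot"),
                 n_failed_resamples = attr(x, "n_failed_resamples"),
                 ci_level = attr(x, "ci_level"),
                 cells_used = attr(x, "cells_used"),
                 seed = attr(x, "seed"))
}

#' Tidy an LDA fit (marker contributions)
#' @param x a `cyto_lda`.
#' @param ... unused.
#' @return The contributions tibble (`marker`, `axis`, `loading`).
#' @export
tidy.cyto_lda <- function(x, ...) {
  x$contributions
}

#' One-row summary of an LDA fit
#' @param x a `cyto_lda`.
#' @param ... unused.
#' @return Tibble with group count, marker count, eigenvalues and lambda.
#' @export
glance.cyto_lda <- function(x, ...) {
  tibble::tibble(n_groups = length(x$classes),
                 n_markers = nrow(x$axes),
                 n_axes = ncol(x$axes),
                 eigenvalue_1 = x$eigenvalues[1],
                 lambda = x$lambda)
}
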