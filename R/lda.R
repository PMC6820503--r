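#' Per-donor median marker profiles
#'
#' Collapses each donor-sample's gated cells to the median arcsinh
#' expression per marker (midpoint convention for even counts — the exact
#' sample median). Donors are the independent units, so discriminant
#' analysis runs on these profiles rather than on cells, which would
#' pseudo-replicate. Donors with no cells are excluded with a warning.
#'
#' @param samples named list of arcsinh `cell_tbl` or one combined
#'   `cell_tbl` with `donor` and `group` columns.
#' @param markers markers to summarise.
#' @param design optional `study_design` supplying group labels when the
#'   cells carry none.
#' @return A `donor_summary` tibble: `donor`, `group`, one column per
#'   marker.
#' @export
donor_medians <- function(samples, markers, design = NULL) {
  tab <- if (inherits(samples, "cell_tbl")) samples else bind_cells(samples)
  missing <- setdiff(markers, names(tab))
  if (length(missing)) {
    stop("markers missing from the data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(as.data.frame(tab))
  if (!is.null(design)) {
    df$group <- design$group[match(df$donor, design$donor)]
  }
  if (!"group" %in% names(df) || anyNA(df$group)) {
    stop("cells need group labels (supply `design`)", call. = FALSE)
  }
  out <- df |>
    dplyr::group_by(.data$donor, .data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(markers),
                                   ~ stats::median(.x)),
                     .groups = "drop")
  if (!is.null(design)) {
    absent <- setdiff(design$donor[design$group %in% out$group],
                      out$donor)
    if (length(absent)) {
      warning("donors with no gated cells excluded: ",
              paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  out <- out[order(out$donor), , drop = FALSE]
  class(out) <- c("donor_summary", class(out))
  out
}

#' Fisher linear discriminant analysis of donor profiles
#'
#' Computes within-class scatter `S_W` and between-class scatter `S_B` of
#' the centered donor-by-marker matrix and takes discriminant axes as the
#' leading eigenvectors of `(S_W + lambda I)^{-1} S_B` (solved via a
#' symmetric whitening decomposition, so eigenvalues are real and
#' nonnegative). Axes are unit-norm with the largest-magnitude loading
#' made positive; marker contributions are axis coefficients scaled by the
#' pooled within-class sd of each marker, so they are comparable across
#' markers.
#'
#' @param summary a `donor_summary` from [donor_medians()] (or any tibble
#'   with `donor`, `group` and numeric marker columns).
#' @param lambda ridge shrinkage added to `S_W`. Default `NULL`: 0 when
#'   there are more donors than markers, else
#'   `1e-3 * trace(S_W) / n_markers`, which keeps near-singular
#'   wide-panel problems solvable.
#' @return A list of class `cyto_lda`: `axes` (markers x axes), descending
#'   `eigenvalues`, `projections` (tibble donor, group, LD1, LD2, ...),
#'   `contributions` (tibble marker, axis, loading), `lambda`, `means`.
#' @export
fit_lda <- function(summary, lambda = NULL) {
  mk <- setdiff(names(summary), c("donor", "group"))
  X <- as.matrix(as.data.frame(summary)[, mk, drop = FALSE])
  g <- as.character(summary$group)
  classes <- sort(unique(g))
  if (length(classes) < 2L) {
    stop("discriminant analysis needs at least 2 groups", call. = FALSE)
  }
  if (any(table(g) < 2L)) {
    stop("every group needs at least 2 donor rows", call. = FALSE)
  }
  n <- nrow(X)
  p <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)

  Sw <- matrix(0, p, p, dimnames = list(mk, mk))
  Sb <- matrix(0, p, p, dimnames = list(mk, mk))
  for (cl in classes) {
    rows <- Xc[g == cl, , drop = FALSE]
    m_cl <- colMeans(rows)
    rc <- sweep(rows, 2, m_cl)
    Sw <- Sw + crossprod(rc)
    Sb <- Sb + nrow(rows) * tcrossprod(m_cl)
  }

  if (is.null(lambda)) {
    lambda <- if (p >= n) 1e-3 * sum(diag(Sw)) / p else 0
  }
  Swl <- Sw + diag(lambda, p)
  L <- tryCatch(chol(Swl), error = function(e) NULL)
  if (is.null(L)) {
    stop("within-class scatter is singular; use lambda > 0", call. = FALSE)
  }
  # whiten: eigenproblem of Li' Sb Li, Li = inv(chol), symmetric PSD
  M <- backsolve(L, t(backsolve(L, t(Sb), transpose = TRUE)),
                 transpose = TRUE)
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  k <- min(length(classes) - 1L, p)
  vals <- pmax(eg$values[seq_len(k)], 0)
  axes <- backsolve(L, eg$vectors[, seq_len(k), drop = FALSE])
  # unit norm, largest-|loading| entry positive
  for (j in seq_len(k)) {
    v <- axes[, j] / sqrt(sum(axes[, j]^2))
    imax <- which.max(abs(v))
    if (v[imax] < 0) v <- -v
    axes[, j] <- v
  }
  dimnames(axes) <- list(mk, paste0("LD", seq_len(k)))

  proj <- Xc %*% axes
  projections <- dplyr::bind_cols(
    tibble::tibble(donor = summary$donor, group = g),
    tibble::as_tibble(proj))

  pooled_sd <- sqrt(diag(Sw) / (n - length(classes)))
  contributions <- tidyr::expand_grid(axis = colnames(axes), marker = mk) |>
    dplyr::mutate(loading = purrr::map2_dbl(
      .data$marker, .data$axis, ~ axes[.x, .y] * pooled_sd[.x])) |>
    dplyr::select("marker", "axis", "loading")

  structure(list(axes = axes, eigenvalues = vals,
                 projections = projections,
                 contributions = contributions,
                 lambda = lambda, means = mu, classes = classes),
            class = "cyto_lda")
}

#' Rank markers by discriminant contribution
#'
#' Orders markers by descending absolute standardized loading on one
#' discriminant axis (ties alphabetical): the "markers that best separate"
#' reading of a discriminant plot.
#'
#' @param result a `cyto_lda`.
#' @param axis axis index (1 = LD1) or name.
#' @return Character vector of markers, most contributing first.
#' @export
rank_markers <- function(result, axis = 1L) {
  ax <- if (is.numeric(axis)) paste0("LD", axis) else axis
  if (!ax %in% colnames(result$axes)) {
    stop("axis ", ax, " does not exist", call. = FALSE)
  }
  ct <- result$contributions[result$contributions$axis == ax, ]
  ct <- ct[order(-abs(ct$loading), ct$marker), ]
  ct$marker
}

#' @export
print.cyto_lda <- function(x, ...) {
  cat(sprintf("Fisher LDA: %d groups, %d markers, lambda = %g\n",
              length(x$classes), nrow(x$axes), x$lambda))
  cat("eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}
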