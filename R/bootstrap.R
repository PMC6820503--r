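#' Specify a cell-level logistic model with donor bootstrap
#'
#' The contrast is an ordered pair `(reference, comparison)`: cells are
#' coded 0 for the reference group and 1 for the comparison group, so a
#' positive log-odds means the marker predicts the comparison state.
#'
#' @param contrast character(2): reference then comparison group label,
#'   e.g. `c("control", "pregnant")` or `c("postpartum", "pregnant")`.
#' @param markers predictor markers (arcsinh scale, standardized
#'   internally).
#' @param n_boot number of donor-bootstrap resamples (default 200); 0
#'   gives point estimates only.
#' @param ci_level confidence level for the percentile interval (default
#'   0.95, the "bar does not cross zero" convention).
#' @param cells_per_donor balancing subsample size per donor; default
#'   `NULL` means downsample every donor to the smallest donor cell count,
#'   so no donor dominates the cell-level likelihood. Use `Inf` to keep
#'   all cells.
#' @param paired if `TRUE`, only complete pregnant/post-partum pairs enter
#'   and the bootstrap resamples pairs as single units.
#' @param seed integer; expands deterministically into the subsampling
#'   stream and one stream per resample.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(contrast, markers, n_boot = 200L, ci_level = 0.95,
                       cells_per_donor = NULL, paired = FALSE, seed = 1L) {
  stopifnot(length(contrast) == 2L, contrast[1] != contrast[2])
  if (ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must lie in (0, 1)", call. = FALSE)
  }
  if (n_boot < 0) stop("n_boot must be nonnegative", call. = FALSE)
  structure(list(contrast = as.character(contrast),
                 markers = as.character(markers),
                 n_boot = as.integer(n_boot),
                 ci_level = ci_level,
                 cells_per_donor = cells_per_donor,
                 paired = isTRUE(paired),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Donor-bootstrap logistic marker effects
#'
#' The core analysis: a cell-level logistic GLM in which standardized
#' arcsinh marker expressions jointly predict which contrast group a cell's
#' donor belongs to, with uncertainty from a donor-stratified cluster
#' bootstrap. Cells from one donor are correlated, so resampling cells
#' would understate uncertainty; resampling whole donors (with
#' replacement, within group, preserving group sizes; pairs as units for
#' paired contrasts) propagates between-donor heterogeneity into the
#' intervals. A marker is flagged significant when its percentile CI
#' excludes zero.
#'
#' Procedure: (1) optionally downsample each donor to a common cell count;
#' (2) standardize markers once on the full assembled contrast data and
#' reuse that scaling in every refit, keeping all resampled coefficients
#' on one scale; (3) point estimate from the full data (a tiny ridge,
#' 1e-6 on slopes only, is applied if the full fit is separated, to return
#' a finite estimate); (4) `n_boot` donor resamples, refitting each;
#' separated or failed refits are counted in `n_failed_resamples` and
#' excluded from the interval; (5) percentile CI at `ci_level`.
#'
#' @param samples named list of arcsinh-scale `cell_tbl` (one per
#'   donor-sample) or a single combined `cell_tbl` with a `donor` column.
#' @param design a `study_design`.
#' @param spec a [model_spec()].
#' @return A `marker_effects` tibble: `marker`, `estimate`, `ci_low`,
#'   `ci_high`, `significant`, `direction`
#'   (`predicts_comparison` / `predicts_reference` / `none`), with the
#'   contrast, seed, bootstrap draws and failure count as attributes.
#' @export
bootstrap_glm <- function(samples, design, spec) {
  stopifnot(inherits(spec, "model_spec"))
  tab <- if (inherits(samples, "cell_tbl")) samples else bind_cells(samples)
  if (scale_state(tab) != "arcsinh") {
    stop("model runs on the arcsinh scale; transform first", call. = FALSE)
  }
  validate_cells(tab, design)
  ref <- spec$contrast[1]
  comp <- spec$contrast[2]
  absent <- setdiff(spec$contrast, design$group)
  if (length(absent)) {
    stop("contrast groups absent from the design: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  keep_design <- design[design$group %in% spec$contrast, , drop = FALSE]
  if (spec$paired) {
    pairs <- design_pairs(design)
    pairs <- pairs[pairs$pregnant %in% keep_design$donor &
                     pairs$postpartum %in% keep_design$donor, , drop = FALSE]
    if (!setequal(spec$contrast, c("pregnant", "postpartum"))) {
      stop("paired contrasts must compare pregnant and postpartum",
           call. = FALSE)
    }
    keep_design <- keep_design[keep_design$donor %in%
                                 c(pairs$pregnant, pairs$postpartum), ,
                               drop = FALSE]
  }
  keep_design <- keep_design[keep_design$donor %in% tab$donor, , drop = FALSE]
  counts <- table(keep_design$group)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("need at least 2 donors with cells in each contrast group",
         call. = FALSE)
  }

  # deterministic seed expansion: subsample stream + one per resample
  set.seed(spec$seed)
  stream <- sample.int(.Machine$integer.max - 1L, 1L + spec$n_boot)

  # balancing subsample, donors in sorted order for order invariance
  donors <- sort(keep_design$donor)
  idx_by_donor <- lapply(stats::setNames(donors, donors),
                         function(d) which(tab$donor == d))
  n_by_donor <- lengths(idx_by_donor)
  if (any(n_by_donor == 0L)) {
    stop("donors without cells in the assembled data: ",
         paste(donors[n_by_donor == 0L], collapse = ", "), call. = FALSE)
  }
  n_sub <- spec$cells_per_donor %||% min(n_by_donor)
  if (is.finite(n_sub)) {
    set.seed(stream[1])
    idx_by_donor <- lapply(idx_by_donor, function(ix) {
      if (length(ix) > n_sub) sort(sample(ix, n_sub)) else ix
    })
  }

  used <- unlist(idx_by_donor, use.names = FALSE)
  sub <- slice_cells(tab, used)
  grp <- keep_design$group[match(sub$donor, keep_design$donor)]
  y <- as.integer(grp == comp)
  std <- standardize_markers(sub, spec$markers)
  kept_markers <- std$scaling$marker[!std$scaling$dropped]

  # re-index donor cells within the subsampled table
  pos_by_donor <- split(seq_len(nrow(sub)), sub$donor)[donors]

  point <- fit_logistic(std$x, y)
  if (point$separated) {
    point <- fit_logistic(std$x, y, ridge = 1e-6)
  }

  # resampling units: donors within sorted-group strata, or pairs
  if (spec$paired) {
    pairs <- pairs[order(pairs$pregnant), , drop = FALSE]
    units <- lapply(seq_len(nrow(pairs)), function(i)
      c(pairs$pregnant[i], pairs$postpartum[i]))
    strata <- list(seq_along(units))
  } else {
    units <- as.list(donors)
    grp_of_unit <- keep_design$group[match(donors, keep_design$donor)]
    strata <- split(seq_along(units), grp_of_unit)  # sorted group names
  }

  n_failed <- 0L
  boot <- NULL
  if (spec$n_boot > 0L) {
    boot <- matrix(NA_real_, spec$n_boot, length(kept_markers),
                   dimnames = list(NULL, kept_markers))
    for (b in seq_len(spec$n_boot)) {
      set.seed(stream[1L + b])
      take <- unlist(lapply(strata, function(s)
        s[sample.int(length(s), length(s), replace = TRUE)]),
        use.names = FALSE)
      rows <- unlist(lapply(take, function(ui)
        unlist(pos_by_donor[units[[ui]]], use.names = FALSE)),
        use.names = FALSE)
      yb <- y[rows]
      if (length(unique(yb)) < 2L) {
        n_failed <- n_failed + 1L
        next
      }
      fit <- fit_logistic(std$x[rows, , drop = FALSE], yb)
      if (fit$separated || !fit$converged) {
        n_failed <- n_failed + 1L
        next
      }
      boot[b, ] <- fit$coef[kept_markers]
    }
    if (n_failed > 0.2 * spec$n_boot) {
      stop("more than 20% of bootstrap resamples failed or separated (",
           n_failed, "/", spec$n_boot, "); consider fewer markers or ",
           "more cells per donor", call. = FALSE)
    }
  }

  est <- point$coef[kept_markers]
  if (spec$n_boot > 0L) {
    ok <- boot[stats::complete.cases(boot), , drop = FALSE]
    alpha <- (1 - spec$ci_level) / 2
    ci <- apply(ok, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    ci_low <- ci[1, ]
    ci_high <- ci[2, ]
    significant <- ci_low > 0 | ci_high < 0
    direction <- ifelse(!significant, "none",
                        ifelse(ci_low > 0, "predicts_comparison",
                               "predicts_reference"))
  } else {
    ci_low <- ci_high <- rep(NA_real_, length(est))
    significant <- rep(FALSE, length(est))
    direction <- rep("none", length(est))
  }

  out <- tibble::tibble(marker = kept_markers,
                        estimate = unname(est),
                        ci_low = unname(ci_low),
                        ci_high = unname(ci_high),
                        significant = unname(significant),
                        direction = unname(direction))
  structure(out,
            contrast = spec$contrast,
            n_boot = spec$n_boot,
            ci_level = spec$ci_level,
            seed = spec$seed,
            n_failed_resamples = n_failed,
            intercept = unname(point$coef["(Intercept)"]),
            scaling = std$scaling,
            boot = boot,
            cells_used = nrow(sub),
            donors_used = donors,
            class = c("marker_effects", class(out)))
}

#' Plot-ready export of a marker-effects table
#'
#' Orders markers by ascending point estimate (ties alphabetical), the
#' layout of a forest plot whose x-axis is the log-odds of the comparison
#' state.
#'
#' @param effects a `marker_effects` table.
#' @return Tibble with `marker`, `estimate`, `ci_low`, `ci_high`,
#'   `significant`, in plot order.
#' @export
effects_table <- function(effects) {
  out <- tibble::as_tibble(effects)[, c("marker", "estimate", "ci_low",
                                        "ci_high", "significant")]
  out[order(out$estimate, out$marker), , drop = FALSE]
}

#' @export
print.marker_effects <- function(x, ...) {
  ctr <- attr(x, "contrast")
  cat(sprintf("# marker_effects: %s vs %s, %d resamples (%d failed)\n",
              ctr[1], ctr[2], attr(x, "n_boot"),
              attr(x, "n_failed_resamples")))
  NextMethod()
}
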