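#' Boolean threshold gate trees
#'
#' Manual cytometry gating is replaced by declarative static thresholds: a
#' gate tree is an ordered set of named terminal populations, each defined
#' by a conjunction of per-marker threshold gates (`polarity = "above"`
#' keeps cells strictly above the threshold, `"below"` keeps cells at or
#' below it). Populations are evaluated in order and each cell is assigned
#' to the first population whose conjunction it satisfies, so terminal
#' populations are disjoint by construction.
#'
#' @param gates tibble/data frame with columns `population`, `marker`,
#'   `threshold`, `polarity`.
#' @param scale scale the thresholds are declared on (`"arcsinh"` default).
#' @return A tibble of class `gate_tree`.
#' @export
gate_tree <- function(gates, scale = "arcsinh") {
  g <- tibble::as_tibble(gates)
  stopifnot(all(c("population", "marker", "threshold", "polarity") %in%
                  names(g)))
  bad <- setdiff(unique(g$polarity), c("above", "below"))
  if (length(bad)) {
    stop("gate polarity must be 'above' or 'below', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(g$threshold))) {
    stop("gate thresholds must be finite", call. = FALSE)
  }
  g <- g[, c("population", "marker", "threshold", "polarity")]
  structure(g, scale = scale,
            class = c("gate_tree", class(tibble::tibble())))
}

#' Apply a gate tree to a cell table
#'
#' @param table a `cell_tbl` on the scale the tree declares.
#' @param tree a [gate_tree()].
#' @param panel optional `panel_def`; when supplied, gate markers absent
#'   from the panel are dropped with a warning (cohort panels differ), while
#'   gate markers in the panel but absent from the data still error.
#' @return Named list, one `cell_tbl` per terminal population, each cell in
#'   at most one population; input order preserved within populations.
#' @export
apply_gate_tree <- function(table, tree, panel = NULL) {
  if (scale_state(table) != attr(tree, "scale")) {
    stop("gate tree is declared on the ", attr(tree, "scale"),
         " scale but the table is ", scale_state(table), call. = FALSE)
  }
  if (!is.null(panel)) {
    off_panel <- setdiff(unique(tree$marker), panel$marker)
    if (length(off_panel)) {
      warning("gate markers absent from this panel are skipped: ",
              paste(off_panel, collapse = ", "), call. = FALSE)
      tree <- tree[!tree$marker %in% off_panel, , drop = FALSE]
    }
  }
  missing <- setdiff(unique(tree$marker), names(table))
  if (length(missing)) {
    stop("gate markers missing from the data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pops <- unique(tree$population)
  unassigned <- rep(TRUE, nrow(table))
  out <- vector("list", length(pops))
  names(out) <- pops
  for (pop in pops) {
    g <- tree[tree$population == pop, , drop = FALSE]
    keep <- rep(TRUE, nrow(table))
    for (i in seq_len(nrow(g))) {
      x <- table[[g$marker[i]]]
      keep <- keep & if (g$polarity[i] == "above") x > g$threshold[i]
        else x <= g$threshold[i]
    }
    sel <- keep & unassigned
    unassigned <- unassigned & !sel
    out[[pop]] <- slice_cells(table, which(sel))
  }
  out
}

#' Split gated NK cells into CD56dim and CD56bright subsets
#'
#' The two major peripheral NK subsets are separated on CD56 and CD16:
#' bright cells are CD56-high and CD16-low/negative
#' (`CD56 > cd56_hi & CD16 <= cd16_thr`); dim cells sit between the CD56
#' thresholds with CD16 expressed (`cd56_lo < CD56 <= cd56_hi &
#' CD16 > cd16_thr`). The boundary conventions (`<=` into bright/low,
#' `>` into dim/positive) make the subsets disjoint by construction.
#'
#' @param nk a `cell_tbl` of gated NK cells (arcsinh scale).
#' @param cd56_hi,cd56_lo upper and lower CD56 thresholds, `cd56_lo <
#'   cd56_hi`.
#' @param cd16_thr CD16 threshold.
#' @param cd56,cd16 channel names (defaults `"CD56"`, `"CD16"`).
#' @return List with elements `dim` and `bright`, each a `cell_tbl`.
#' @export
split_nk_subsets <- function(nk, cd56_hi, cd56_lo, cd16_thr,
                             cd56 = "CD56", cd16 = "CD16") {
  if (!(cd56_lo < cd56_hi)) {
    stop("cd56_lo must be strictly below cd56_hi", call. = FALSE)
  }
  missing <- setdiff(c(cd56, cd16), names(nk))
  if (length(missing)) {
    stop("gate markers missing from the data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x56 <- nk[[cd56]]
  x16 <- nk[[cd16]]
  bright <- x56 > cd56_hi & x16 <= cd16_thr
  dim_ <- x56 > cd56_lo & x56 <= cd56_hi & x16 > cd16_thr
  list(dim = slice_cells(nk, which(dim_)),
       bright = slice_cells(nk, which(bright)))
}

#' Per-donor positive / co-expression frequencies
#'
#' For each donor, counts the cells above all of the given marker
#' thresholds (a conjunction, e.g. CD38+NKp46+) and reports the percentage
#' of the donor's cells in the table. Donors with an empty denominator are
#' kept as rows with an `NA` percentage and `empty_denominator = TRUE`
#' rather than silently dropped.
#'
#' @param table a `cell_tbl` (typically one gated population).
#' @param markers character vector of marker names.
#' @param thresholds numeric vector, one threshold per marker.
#' @param population label recorded in the output (default
#'   `"cells"`).
#' @param donors optional character vector of donors that must appear in
#'   the output even if they contribute no cells.
#' @return A `frequency_tbl` tibble with columns `donor`, `population`,
#'   `combination`, `numerator`, `denominator`, `percent`,
#'   `empty_denominator`.
#' @export
positive_frequency <- function(table, markers, thresholds,
                               population = "cells", donors = NULL) {
  if (length(markers) != length(thresholds)) {
    stop("need exactly one threshold per marker", call. = FALSE)
  }
  missing <- setdiff(markers, names(table))
  if (length(missing)) {
    stop("markers missing from the data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  combo <- paste0(markers, "+", collapse = "")
  df <- tibble::tibble(donor = table$donor)
  pos <- rep(TRUE, nrow(table))
  for (i in seq_along(markers)) {
    pos <- pos & table[[markers[i]]] > thresholds[i]
  }
  df$pos <- pos
  agg <- df |>
    dplyr::group_by(.data$donor) |>
    dplyr::summarise(numerator = sum(.data$pos),
                     denominator = dplyr::n(), .groups = "drop")
  if (!is.null(donors)) {
    agg <- dplyr::left_join(tibble::tibble(donor = donors), agg,
                            by = "donor") |>
      dplyr::mutate(numerator = dplyr::coalesce(.data$numerator, 0L),
                    denominator = dplyr::coalesce(.data$denominator, 0L))
  }
  out <- agg |>
    dplyr::mutate(population = population, combination = combo,
                  empty_denominator = .data$denominator == 0L,
                  percent = ifelse(.data$denominator > 0,
                                   100 * .data$numerator / .data$denominator,
                                   NA_real_)) |>
    dplyr::select("donor", "population", "combination", "numerator",
                  "denominator", "percent", "empty_denominator")
  class(out) <- c("frequency_tbl", class(out))
  out
}
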