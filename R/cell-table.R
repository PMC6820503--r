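#' Per-cell expression tables
#'
#' A `cell_tbl` is a tibble with one row per cell: metadata columns
#' (`sample_id`, `donor`, `group`, and optionally `population`) followed by
#' one numeric column per channel. Channel identity and measurement scale
#' travel as attributes so that downstream stages can refuse data on the
#' wrong scale (e.g. gating raw ion counts, or arcsinh-transforming twice).
#'
#' @param values numeric matrix or data frame, rows = cells, columns =
#'   channels.
#' @param channels character vector of unique channel names; defaults to the
#'   column names of `values`.
#' @param meta data frame with one row per cell holding at least a `donor`
#'   column; `sample_id`, `group` and `population` are carried when present.
#'   A single-row `meta` is recycled to all cells.
#' @param scale_state `"raw"` (nonnegative acquisition-scale intensities) or
#'   `"arcsinh"` (variance-stabilized, `asinh(x / cofactor)`).
#' @param cofactor arcsinh cofactor; required when `scale_state = "arcsinh"`.
#'
#' @return A tibble of class `cell_tbl`.
#' @export
#' @examples
#' cell_table(matrix(rexp(6), 3, 2), channels = c("CD38", "NKp46"),
#'            meta = data.frame(donor = "d1", group = "control"))
cell_table <- function(values, channels = colnames(values), meta = NULL,
                       scale_state = c("raw", "arcsinh"), cofactor = NULL) {
  scale_state <- match.arg(scale_state)
  values <- as.matrix(values)
  if (!is.numeric(values) && nrow(values) > 0) {
    stop("`values` must be numeric", call. = FALSE)
  }
  if (is.null(channels)) stop("channel names are required", call. = FALSE)
  channels <- as.character(channels)
  if (length(channels) != ncol(values)) {
    stop("number of channel names (", length(channels),
         ") does not match number of value columns (", ncol(values), ")",
         call. = FALSE)
  }
  if (anyDuplicated(channels)) {
    stop("channel names must be unique: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(values) > 0 && !all(is.finite(values))) {
    stop("cell values must be finite", call. = FALSE)
  }
  if (scale_state == "raw" && nrow(values) > 0 && any(values < 0)) {
    stop("raw-scale values must be nonnegative", call. = FALSE)
  }
  if (scale_state == "arcsinh" &&
      (is.null(cofactor) || !is.finite(cofactor) || cofactor <= 0)) {
    stop("arcsinh-scale tables need a positive `cofactor`", call. = FALSE)
  }

  n <- nrow(values)
  if (is.null(meta)) {
    meta <- tibble::tibble(donor = rep(NA_character_, n))
  }
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) == 1L && n != 1L) {
    meta <- meta[rep(1L, n), , drop = FALSE]
  }
  if (nrow(meta) != n) {
    stop("`meta` has ", nrow(meta), " rows but `values` has ", n, " cells",
         call. = FALSE)
  }
  keep <- intersect(c("sample_id", "donor", "group", "population"),
                    names(meta))
  meta <- meta[, keep, drop = FALSE]
  if (!"donor" %in% names(meta)) meta$donor <- NA_character_

  if (any(channels %in% names(meta))) {
    stop("channel names clash with metadata columns: ",
         paste(intersect(channels, names(meta)), collapse = ", "),
         call. = FALSE)
  }
  colnames(values) <- channels
  out <- dplyr::bind_cols(meta, tibble::as_tibble(values))
  new_cell_tbl(out, channels, scale_state, cofactor)
}

new_cell_tbl <- function(df, channels, scale_state, cofactor = NULL) {
  structure(df,
            channels = channels,
            scale_state = scale_state,
            cofactor = if (scale_state == "arcsinh") cofactor else NULL,
            class = c("cell_tbl", class(tibble::tibble())))
}

#' @export
print.cell_tbl <- function(x, ...) {
  cat(sprintf("# cell_tbl: %d cells x %d channels [%s%s]\n",
              nrow(x), length(channel_names(x)), scale_state(x),
              if (scale_state(x) == "arcsinh")
                sprintf(", cofactor %g", attr(x, "cofactor")) else ""))
  NextMethod()
}

#' Channel names of a cell table
#' @param x a `cell_tbl`.
#' @return Character vector of channel names, in column order.
#' @export
channel_names <- function(x) {
  ch <- attr(x, "channels")
  if (is.null(ch)) setdiff(names(x), c("sample_id", "donor", "group", "population")) else ch
}

#' Measurement scale of a cell table
#' @param x a `cell_tbl`.
#' @return `"raw"` or `"arcsinh"`.
#' @export
scale_state <- function(x) {
  s <- attr(x, "scale_state")
  if (is.null(s)) "raw" else s
}

#' Extract the expression matrix from a cell table
#'
#' @param x a `cell_tbl`.
#' @param channels channels to extract (default all).
#' @return Numeric matrix, rows = cells, columns = `channels`.
#' @export
channel_matrix <- function(x, channels = channel_names(x)) {
  missing <- setdiff(channels, names(x))
  if (length(missing)) {
    stop("channels not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(as.data.frame(x)[, channels, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

cell_meta <- function(x) {
  keep <- intersect(c("sample_id", "donor", "group", "population"), names(x))
  tibble::as_tibble(as.data.frame(x)[, keep, drop = FALSE])
}

# Rebuild the subclass after a tibble verb has stripped attributes.
restore_cell_tbl <- function(df, template, channels = channel_names(template)) {
  new_cell_tbl(tibble::as_tibble(df), channels,
               scale_state(template), attr(template, "cofactor"))
}

#' Subset the cells of a cell table by row index or predicate result
#' @param x a `cell_tbl`.
#' @param i integer or logical row index.
#' @return A `cell_tbl` with the selected cells, attributes preserved.
#' @export
slice_cells <- function(x, i) {
  restore_cell_tbl(as.data.frame(x)[i, , drop = FALSE], x)
}

#' Bind cell tables row-wise
#' @param ... `cell_tbl` objects sharing channels and scale.
#' @return A single `cell_tbl`.
#' @export
bind_cells <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]])) {
    tabs <- tabs[[1]]
  }
  stopifnot(length(tabs) >= 1L)
  ch <- channel_names(tabs[[1]])
  ss <- scale_state(tabs[[1]])
  for (t in tabs[-1]) {
    if (!identical(channel_names(t), ch) || !identical(scale_state(t), ss)) {
      stop("cell tables differ in channels or scale", call. = FALSE)
    }
  }
  restore_cell_tbl(dplyr::bind_rows(lapply(tabs, as.data.frame)), tabs[[1]])
}

#' Check a cell table against a study design
#'
#' Every donor appearing in the cells must be a donor of the design.
#'
#' @param x a `cell_tbl`.
#' @param design a `study_design`.
#' @return `x`, invisibly, or an error listing unknown donors.
#' @export
validate_cells <- function(x, design) {
  unknown <- setdiff(unique(stats::na.omit(x$donor)), design$donor)
  if (length(unknown)) {
    stop("donors present in cells but absent from the study design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
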