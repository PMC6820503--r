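#' Read a delimited cell table
#'
#' A first-class plain-text alternative to FCS: a CSV/TSV with a header row,
#' where some columns are metadata (donor, group, ...) and the rest are
#' channels. Cells are never reordered.
#'
#' @param path path to a delimited file with header.
#' @param meta_cols names of metadata columns; the remaining columns are
#'   channels. Defaults to whichever of `sample_id`, `donor`, `group`,
#'   `population` appear in the header.
#' @param scale_state scale of the stored values (`"raw"` default).
#' @param cofactor arcsinh cofactor when `scale_state = "arcsinh"`.
#' @param sep field separator (`","` default; use `"\t"` for TSV).
#' @param design optional `study_design`; when given, the cell donors are
#'   checked against it and unknown donors raise an error.
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path, meta_cols = NULL,
                            scale_state = c("raw", "arcsinh"),
                            cofactor = NULL, sep = ",", design = NULL) {
  scale_state <- match.arg(scale_state)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(meta_cols)) {
    meta_cols <- intersect(c("sample_id", "donor", "group", "population"),
                           names(df))
  }
  channels <- setdiff(names(df), meta_cols)
  if (!length(channels)) stop("no channel columns found", call. = FALSE)
  out <- cell_table(as.matrix(df[, channels, drop = FALSE]),
                    channels = channels,
                    meta = df[, meta_cols, drop = FALSE],
                    scale_state = scale_state, cofactor = cofactor)
  if (!is.null(design)) validate_cells(out, design)
  out
}

#' Write a cell table as delimited text
#' @param table a `cell_tbl`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path, sep = ",") {
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a study design table
#'
#' Expects a delimited file with columns `donor`, `group`, and optionally
#' `cohort` and `paired_with`; all [study_design()] invariants (valid group
#' labels, bijective pregnant/post-partum pairing) are enforced.
#'
#' @param path path to a CSV/TSV design file.
#' @param sep field separator.
#' @return A `study_design`.
#' @export
read_design <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  study_design(df)
}

#' Write a study design table
#' @param design a `study_design`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path, sep = ",") {
  utils::write.table(as.data.frame(design), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gate definitions from a YAML file
#'
#' The file holds named populations, each an ordered conjunction of
#' threshold gates:
#' ```yaml
#' scale: arcsinh
#' populations:
#'   NK:
#'     - {marker: CD3,  threshold: 1.5, polarity: below}
#'     - {marker: CD56, threshold: 1.2, polarity: above}
#' ```
#'
#' @param path path to a YAML gate file.
#' @return A [gate_tree()].
#' @export
read_gates <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$populations)) {
    stop("gate file has no `populations` block", call. = FALSE)
  }
  rows <- purrr::imap_dfr(spec$populations, function(gates, pop) {
    purrr::map_dfr(gates, function(g) {
      tibble::tibble(population = pop,
                     marker = as.character(g$marker),
                     threshold = as.numeric(g$threshold),
                     polarity = as.character(g$polarity))
    })
  })
  gate_tree(rows, scale = spec$scale %||% "arcsinh")
}

#' Write gate definitions to a YAML file
#' @param tree a `gate_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gates <- function(tree, path) {
  pops <- lapply(split(tree, tree$population)[unique(tree$population)],
                 function(d) {
                   lapply(seq_len(nrow(d)), function(i) {
                     list(marker = d$marker[i],
                          threshold = d$threshold[i],
                          polarity = d$polarity[i])
                   })
                 })
  yaml::write_yaml(list(scale = attr(tree, "scale"), populations = pops),
                   path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
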