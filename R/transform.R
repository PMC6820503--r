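#' Arcsinh-transform a raw cell table
#'
#' The standard variance-stabilizing transform for mass cytometry:
#' `asinh(x / cofactor)`, elementwise over every channel. Transforming an
#' already-transformed table is a contract error, caught via the table's
#' scale state.
#'
#' @param table a raw-scale `cell_tbl`.
#' @param cofactor positive real; 5 is the mass-cytometry convention.
#' @return An arcsinh-scale `cell_tbl`.
#' @export
arcsinh_transform <- function(table, cofactor = 5) {
  if (scale_state(table) != "raw") {
    stop("table is already on the ", scale_state(table),
         " scale; refusing to transform twice", call. = FALSE)
  }
  if (!is.finite(cofactor) || cofactor <= 0) {
    stop("cofactor must be a positive real", call. = FALSE)
  }
  vals <- asinh(channel_matrix(table) / cofactor)
  cell_table(vals, channels = channel_names(table), meta = cell_meta(table),
             scale_state = "arcsinh", cofactor = cofactor)
}
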