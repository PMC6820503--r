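#' Read an FCS 3.0/3.1 file into a cell table
#'
#' Parses the header, TEXT and DATA segments of a flow/mass-cytometry
#' standard file. List-mode data with float (`$DATATYPE F`), double (`D`)
#' or unsigned integer (`I`, 8/16/32/64-bit) events are supported, in either
#' byte order. Channel names come from the `$PnN` short-name keyword,
#' falling back to the `$PnS` stain name. Cells are returned in acquisition
#' order, on the raw scale.
#'
#' Donor and group metadata are deliberately not read from the file:
#' repository datasets store one file per donor-sample and link files to the
#' design table by name, so callers attach metadata afterwards (see `meta`).
#'
#' @param path path to an FCS file.
#' @param meta optional single-row data frame of metadata (`donor`, `group`,
#'   ...) applied to every cell.
#' @return A raw-scale [cell_table()].
#' @export
read_fcs <- function(path, meta = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("not an FCS 3.0/3.1 file (header version '", version, "')",
         call. = FALSE)
  }
  offs <- suppressWarnings(as.integer(vapply(0:5, function(i) {
    trimws(substr(header, 11 + 8 * i, 18 + 8 * i))
  }, character(1))))
  if (any(is.na(offs[1:2]))) {
    stop("malformed FCS header: unreadable TEXT offsets", call. = FALSE)
  }
  txt <- read_fcs_text(con, offs[1], offs[2])

  kw <- function(key, default = NULL) {
    v <- txt[[toupper(key)]]
    if (is.null(v)) default else v
  }
  need <- function(key) {
    v <- kw(key)
    if (is.null(v)) stop("missing required FCS keyword ", key, call. = FALSE)
    v
  }

  mode <- need("$MODE")
  if (toupper(mode) != "L") {
    stop("unsupported $MODE '", mode, "' (only list mode)", call. = FALSE)
  }
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "D", "I")) {
    stop("unsupported $DATATYPE '", dtype, "'", call. = FALSE)
  }
  byteord <- need("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))

  channels <- vapply(seq_len(n_par), function(i) {
    nm <- kw(sprintf("$P%dN", i))
    if (is.null(nm) || !nzchar(trimws(nm))) nm <- kw(sprintf("$P%dS", i))
    if (is.null(nm) || !nzchar(trimws(nm))) nm <- sprintf("P%d", i)
    trimws(nm)
  }, character(1))
  channels <- make.unique(channels, sep = "_")

  data_beg <- offs[3]
  data_end <- offs[4]
  if (is.na(data_beg) || data_beg == 0L) {
    data_beg <- as.integer(kw("$BEGINDATA", "0"))
    data_end <- as.integer(kw("$ENDDATA", "0"))
  }
  if (n_tot > 0 && (is.na(data_beg) || data_beg <= 0)) {
    stop("malformed FCS file: no DATA segment offset ($BEGINDATA)",
         call. = FALSE)
  }

  if (n_tot == 0L) {
    values <- matrix(numeric(0), nrow = 0, ncol = n_par)
  } else {
    seek(con, data_beg)
    n_val <- n_par * n_tot
    if (dtype == "F") {
      x <- readBin(con, "numeric", n = n_val, size = 4L, endian = endian)
    } else if (dtype == "D") {
      x <- readBin(con, "numeric", n = n_val, size = 8L, endian = endian)
    } else {
      bits <- unique(as.integer(vapply(seq_len(n_par), function(i)
        need(sprintf("$P%dB", i)), character(1))))
      if (length(bits) != 1L || !bits %in% c(8L, 16L, 32L, 64L)) {
        stop("unsupported integer layout in $PnB (need uniform 8/16/32/64)",
             call. = FALSE)
      }
      if (bits == 64L) {
        x <- readBin(con, "numeric", n = n_val, size = 8L, endian = endian)
      } else {
        x <- readBin(con, "integer", n = n_val, size = bits / 8L,
                     signed = bits < 32L, endian = endian)
        if (bits == 32L) x[x < 0] <- x[x < 0] + 2^32
        x <- as.numeric(x)
      }
    }
    if (length(x) != n_val) {
      stop("truncated DATA segment: expected ", n_val, " values, got ",
           length(x), call. = FALSE)
    }
    values <- matrix(x, nrow = n_tot, ncol = n_par, byrow = TRUE)
  }
  cell_table(values, channels = channels, meta = meta, scale_state = "raw")
}

read_fcs_text <- function(con, beg, end) {
  seek(con, beg)
  raw_txt <- readChar(con, end - beg + 1L, useBytes = TRUE)
  delim <- substr(raw_txt, 1, 1)
  body <- substr(raw_txt, 2, nchar(raw_txt))
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  parts <- parts[seq_len(length(parts) %/% 2 * 2)]
  if (length(parts) < 2L) {
    stop("malformed FCS TEXT segment (no keyword/value pairs)",
         call. = FALSE)
  }
  keys <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  vals <- parts[seq(2, length(parts), by = 2)]
  stats::setNames(as.list(vals), keys)
}

#' Write a cell table to an FCS 3.1 file
#'
#' Writes a single little-endian float32 list-mode dataset. Only raw-scale
#' tables go to disk: arcsinh-transformed values are an analysis-internal
#' representation, and persisting them would make the file lie about its
#' scale to any other FCS consumer.
#'
#' @param table a raw-scale `cell_tbl`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path) {
  if (scale_state(table) != "raw") {
    stop("only raw-scale tables are written to FCS; ",
         "inverse-transform or regenerate raw values first", call. = FALSE)
  }
  channels <- channel_names(table)
  values <- channel_matrix(table)
  n_par <- length(channels)
  n_tot <- nrow(values)

  kws <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot)
  )
  for (i in seq_len(n_par)) {
    rng <- max(values[, i], 1, na.rm = TRUE)
    kws[sprintf("$P%dN", i)] <- channels[i]
    kws[sprintf("$P%dB", i)] <- "32"
    kws[sprintf("$P%dE", i)] <- "0,0"
    kws[sprintf("$P%dR", i)] <- format(ceiling(rng), scientific = FALSE)
  }

  build_text <- function(kws, data_beg, data_end) {
    kws["$BEGINDATA"] <- as.character(data_beg)
    kws["$ENDDATA"] <- as.character(data_end)
    paste0("/", paste0(names(kws), "/", unname(kws), "/", collapse = ""))
  }
  # data offsets depend on TEXT length; iterate to a fixed point
  text_beg <- 58L
  data_beg <- 0L
  data_end <- 0L
  for (k in 1:5) {
    txt <- build_text(kws, data_beg, data_end)
    new_beg <- text_beg + nchar(txt, type = "bytes")
    new_end <- if (n_tot > 0) new_beg + 4L * n_par * n_tot - 1L else 0L
    if (new_beg == data_beg && new_end == data_end) break
    data_beg <- new_beg
    data_end <- new_end
  }
  txt <- build_text(kws, data_beg, data_end)
  text_end <- text_beg + nchar(txt, type = "bytes") - 1L

  fmt8 <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ",
                   fmt8(text_beg), fmt8(text_end),
                   fmt8(if (data_end <= 99999999 && n_tot > 0) data_beg else 0),
                   fmt8(if (data_end <= 99999999 && n_tot > 0) data_end else 0),
                   fmt8(0), fmt8(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(txt, con, eos = NULL, useBytes = TRUE)
  if (n_tot > 0) {
    writeBin(as.numeric(t(values)), con, size = 4L, endian = "little")
  }
  invisible(path)
}
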