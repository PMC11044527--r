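#' Event matrix: one listmode acquisition
#'
#' The in-memory form of an FCS acquisition: an events-by-channels matrix of
#' nonnegative intensities plus per-channel metadata.
#'
#' @param data Numeric matrix, events in rows, channels in columns. All
#'   values must be finite; compensated fluorescence may be negative.
#' @param channels Data frame with one row per channel and columns
#'   `index` (1-based position), `short_name` (instrument label, `$PnN`),
#'   `marker` (panel marker, `$PnS`, may be `""`), `range` (max instrument
#'   value, `$PnR`).
#' @param sample_id Character scalar identifying the sample.
#' @return An object of class `event_matrix`.
#' @export
event_matrix <- function(data, channels, sample_id = "sample") {
  em <- structure(
    list(data = data, channels = channels, sample_id = sample_id),
    class = "event_matrix"
  )
  validate_event_matrix(em)
}

validate_event_matrix <- function(em) {
  if (!inherits(em, "event_matrix")) {
    stop_cd26("not an event_matrix", class = "cd26_parameter_error")
  }
  if (!is.matrix(em$data) || !is.numeric(em$data)) {
    stop_cd26("event data must be a numeric matrix",
              class = "cd26_parameter_error")
  }
  ch <- em$channels
  need <- c("index", "short_name", "marker", "range")
  if (!is.data.frame(ch) || !all(need %in% names(ch))) {
    stop_cd26("channels must be a data frame with columns index, short_name, marker, range",
              class = "cd26_parameter_error")
  }
  if (ncol(em$data) != nrow(ch)) {
    stop_cd26("number of data columns must equal number of channel entries",
              class = "cd26_parameter_error")
  }
  if (anyDuplicated(ch$index)) {
    stop_cd26("channel indices must be unique", class = "cd26_parameter_error")
  }
  mk <- ch$marker[!is.na(ch$marker) & nzchar(ch$marker)]
  if (anyDuplicated(mk)) {
    stop_cd26("non-empty marker names must be unique",
              class = "cd26_parameter_error")
  }
  # compensated fluorescence legitimately dips below zero; only finiteness
  # is enforced
  if (length(em$data) && !all(is.finite(em$data))) {
    stop_cd26("all intensities must be finite",
              class = "cd26_parameter_error")
  }
  em
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("event_matrix '%s': %d events x %d channels\n",
              x$sample_id, nrow(x$data), ncol(x$data)))
  lab <- ifelse(nzchar(x$channels$marker),
                paste0(x$channels$short_name, " <", x$channels$marker, ">"),
                x$channels$short_name)
  cat("  channels:", paste(lab, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.event_matrix <- function(x) dim(x$data)

# ---------------------------------------------------------------------------
# FCS binary format
# ---------------------------------------------------------------------------

fcs_header_offsets <- function(raw58) {
  txt <- rawToChar(raw58)
  pick <- function(a, b) {
    v <- suppressWarnings(as.numeric(trimws(substr(txt, a, b))))
    if (is.na(v)) 0 else v
  }
  list(version = substr(txt, 1, 6),
       text_start = pick(11, 18), text_end = pick(19, 26),
       data_start = pick(27, 34), data_end = pick(35, 42))
}

parse_fcs_text <- function(raw_text) {
  delim <- rawToChar(raw_text[1])
  body <- rawToChar(raw_text[-1])
  # Keyword segment is /key/value/.../; a trailing delimiter is standard.
  toks <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(toks) %% 2L == 1L) toks <- c(toks, "")
  keys <- toks[seq(1, length(toks), by = 2)]
  vals <- toks[seq(2, length(toks), by = 2)]
  names(vals) <- toupper(trimws(keys))
  vals
}

kw <- function(kws, key, default = NULL) {
  v <- kws[[toupper(key)]]
  if (is.null(v) || !nzchar(v)) default else v
}

#' Read an FCS 3.0/3.1 listmode file
#'
#' Parses the header, TEXT and DATA segments of a Flow Cytometry Standard
#' file. List-mode data of type `F` (32-bit float), `D` (64-bit float) and
#' `I` (16/32-bit unsigned integer) are supported, in either byte order.
#' Intensities are assumed to be instrument-processed (compensated); no
#' spillover handling is performed.
#'
#' @param path Path to an FCS file.
#' @return An [event_matrix()] whose event count equals the file's declared
#'   `$TOT` and whose channel metadata come from the `$PnN`/`$PnS`/`$PnR`
#'   keywords.
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) {
    stop_cd26(paste0("file not found: ", path), class = "cd26_io_error")
  }
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (sz < 58) {
    stop_cd26("file too short to hold an FCS header",
              class = "cd26_format_error")
  }
  hd <- fcs_header_offsets(readBin(con, "raw", 58))
  if (!hd$version %in% c("FCS3.0", "FCS3.1")) {
    stop_cd26(paste0("unsupported FCS version: ", hd$version),
              class = "cd26_format_error")
  }
  if (hd$text_end < hd$text_start || hd$text_end > sz) {
    stop_cd26("corrupt TEXT segment offsets", class = "cd26_integrity_error")
  }
  seek(con, hd$text_start)
  kws <- parse_fcs_text(readBin(con, "raw", hd$text_end - hd$text_start + 1))

  mode <- toupper(kw(kws, "$MODE", "L"))
  if (mode != "L") {
    stop_cd26("only list-mode ($MODE L) data are supported",
              class = "cd26_format_error")
  }
  dtype <- toupper(kw(kws, "$DATATYPE", "F"))
  if (!dtype %in% c("F", "D", "I")) {
    stop_cd26(paste0("unsupported $DATATYPE: ", dtype),
              class = "cd26_format_error")
  }
  byteord <- kw(kws, "$BYTEORD", "1,2,3,4")
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stop_cd26(paste0("unsupported $BYTEORD: ", byteord),
                           class = "cd26_format_error")
  n_par <- as.integer(kw(kws, "$PAR", "0"))
  n_tot <- as.integer(kw(kws, "$TOT", "0"))
  if (is.na(n_par) || n_par < 1) {
    stop_cd26("missing or invalid $PAR", class = "cd26_format_error")
  }

  bits <- vapply(seq_len(n_par), function(i) {
    as.integer(kw(kws, sprintf("$P%dB", i), "32"))
  }, integer(1))
  if (dtype == "F" && any(bits != 32L)) {
    stop_cd26("$DATATYPE F requires 32-bit parameters",
              class = "cd26_format_error")
  }
  if (dtype == "D" && any(bits != 64L)) {
    stop_cd26("$DATATYPE D requires 64-bit parameters",
              class = "cd26_format_error")
  }
  if (dtype == "I" && !all(bits %in% c(16L, 32L))) {
    stop_cd26("integer data must use 16- or 32-bit parameters",
              class = "cd26_format_error")
  }

  data_start <- hd$data_start
  data_end <- hd$data_end
  if (data_start == 0) data_start <- as.numeric(kw(kws, "$BEGINDATA", "0"))
  if (data_end == 0) data_end <- as.numeric(kw(kws, "$ENDDATA", "0"))
  bytes_per_event <- sum(bits) / 8
  expected <- n_tot * bytes_per_event
  actual <- if (n_tot == 0) 0 else data_end - data_start + 1
  if (actual != expected || (n_tot > 0 && data_end > sz)) {
    stop_cd26(sprintf(
      "DATA segment holds %.0f bytes but $TOT=%d events of %d channels need %.0f",
      max(actual, 0), n_tot, n_par, expected), class = "cd26_integrity_error")
  }

  if (n_tot > 0) {
    seek(con, data_start)
    vals <- if (dtype == "I") {
      if (all(bits == bits[1])) {
        # R restricts unsigned reads to 1/2-byte sizes; 32-bit counts from
        # cytometers stay far below 2^31 so a signed read is lossless
        readBin(con, "integer", n = n_tot * n_par, size = bits[1] / 8,
                signed = bits[1] > 16L, endian = endian)
      } else {
        # mixed widths: read event-wise (rare; small files only)
        unlist(lapply(seq_len(n_tot), function(e) {
          vapply(bits, function(b) {
            readBin(con, "integer", 1, size = b / 8, signed = b > 16L,
                    endian = endian)
          }, numeric(1))
        }))
      }
    } else {
      readBin(con, "numeric", n = n_tot * n_par, size = sum(bits) / 8 / n_par,
              endian = endian)
    }
    if (length(vals) != n_tot * n_par) {
      stop_cd26("DATA segment truncated", class = "cd26_integrity_error")
    }
    mat <- matrix(as.numeric(vals), nrow = n_tot, ncol = n_par, byrow = TRUE)
  } else {
    mat <- matrix(numeric(0), nrow = 0, ncol = n_par)
  }

  channels <- data.frame(
    index = seq_len(n_par),
    short_name = vapply(seq_len(n_par), function(i) {
      kw(kws, sprintf("$P%dN", i), sprintf("P%d", i))
    }, character(1)),
    marker = vapply(seq_len(n_par), function(i) {
      kw(kws, sprintf("$P%dS", i), "")
    }, character(1)),
    range = vapply(seq_len(n_par), function(i) {
      as.numeric(kw(kws, sprintf("$P%dR", i), "262144"))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  sample_id <- kw(kws, "$FIL",
                  tools::file_path_sans_ext(basename(path)))
  event_matrix(mat, channels, sample_id = sample_id)
}

#' Write an event matrix as FCS 3.1
#'
#' Emits list-mode FCS 3.1 with 32-bit floating point data
#' (`$DATATYPE F`, `$BYTEORD 1,2,3,4`), one parameter per channel, the
#' instrument label in `$PnN` and the panel marker in `$PnS`. A re-read
#' with [read_fcs()] reproduces the intensities to single precision.
#'
#' @param em An [event_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fcs <- function(em, path) {
  em <- validate_event_matrix(em)
  n <- nrow(em$data)
  p <- ncol(em$data)
  d <- "/"
  esc <- function(x) gsub(d, paste0(d, d), as.character(x), fixed = TRUE)
  pairs <- c(
    "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
    "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
    "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
    "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
    "$NEXTDATA", "0", "$PAR", as.character(p), "$TOT", as.character(n),
    "$FIL", esc(em$sample_id)
  )
  for (i in seq_len(p)) {
    pairs <- c(pairs,
               sprintf("$P%dB", i), "32",
               sprintf("$P%dE", i), "0,0",
               sprintf("$P%dN", i), esc(em$channels$short_name[i]),
               sprintf("$P%dR", i), format(em$channels$range[i],
                                           scientific = FALSE))
    if (nzchar(em$channels$marker[i])) {
      pairs <- c(pairs, sprintf("$P%dS", i), esc(em$channels$marker[i]))
    }
  }
  text_template <- paste0(d, paste(pairs, collapse = d), d)
  text_start <- 58
  # data offsets appear inside TEXT; zero-padded fixed width keeps the
  # segment length independent of their value
  text_len <- nchar(sub("%BD%", "00000000",
                        sub("%ED%", "00000000", text_template), fixed = TRUE),
                    type = "bytes")
  text_end <- text_start + text_len - 1
  if (n > 0) {
    data_start <- text_end + 1
    data_end <- data_start + 4 * n * p - 1
  } else {
    data_start <- 0
    data_end <- 0
  }
  text <- sub("%BD%", sprintf("%08d", data_start),
              sub("%ED%", sprintf("%08d", data_end), text_template),
              fixed = TRUE)
  hdr <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                 text_start, text_end,
                 if (data_end <= 99999999) data_start else 0,
                 if (data_end <= 99999999) data_end else 0,
                 0, 0)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  if (n > 0) {
    writeBin(as.numeric(t(em$data)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Export the event table as CSV
#'
#' One column per channel, header = marker name where present, otherwise the
#' instrument short name.
#'
#' @param em An [event_matrix()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_events_csv <- function(em, path) {
  em <- validate_event_matrix(em)
  hdr <- ifelse(nzchar(em$channels$marker), em$channels$marker,
                em$channels$short_name)
  df <- as.data.frame(em$data)
  names(df) <- hdr
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Panel resolution
# ---------------------------------------------------------------------------

#' Panel configuration
#'
#' An explicit marker-to-channel mapping for the seven-marker panel
#' (FSC, SSC, CD45, CD34, CD38, CD26, CD3), used to override label-based
#' matching when instrument annotations are unreliable.
#'
#' @param marker_to_channel Named integer vector mapping each of the seven
#'   required markers to a distinct 1-based column index.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(marker_to_channel) {
  m <- marker_to_channel
  if (is.null(names(m)) || !setequal(names(m), PANEL_MARKERS)) {
    stop_cd26(paste0("panel config must map exactly the markers: ",
                     paste(PANEL_MARKERS, collapse = ", ")),
              class = "cd26_panel_error")
  }
  m <- vapply(m, check_count, integer(1), name = "channel index", min = 1)
  if (anyDuplicated(m)) {
    stop_cd26("panel markers must map to distinct channels",
              class = "cd26_panel_error")
  }
  structure(list(marker_to_channel = m[PANEL_MARKERS]),
            class = "panel_config")
}

marker_pattern <- function(marker) {
  # word-ish boundaries: 'CD3' must not match 'CD34' or 'CD38'
  sprintf("(^|[^A-Za-z0-9])%s([^0-9]|$)", marker)
}

#' Resolve the seven-marker panel against channel metadata
#'
#' Matches each required marker (FSC, SSC, CD45, CD34, CD38, CD26, CD3)
#' case-insensitively against the channels' stain labels (`marker` field,
#' FCS `$PnS`), falling back to the instrument short name (`$PnN`). Matching
#' respects token boundaries so that CD3 never claims a CD34 or CD38
#' channel. An explicit [panel_config()] bypasses label matching entirely.
#'
#' @param em An [event_matrix()].
#' @param cfg Optional [panel_config()]; returned verbatim when supplied.
#' @return Named integer vector mapping each marker to its column index.
#' @export
resolve_panel <- function(em, cfg = NULL) {
  em <- validate_event_matrix(em)
  if (!is.null(cfg)) {
    if (!inherits(cfg, "panel_config")) cfg <- panel_config(cfg)
    bad <- cfg$marker_to_channel[cfg$marker_to_channel > ncol(em$data)]
    if (length(bad)) {
      stop_cd26("panel config maps markers beyond the channel count",
                class = "cd26_panel_error")
    }
    return(cfg$marker_to_channel)
  }
  find_one <- function(marker) {
    pat <- marker_pattern(marker)
    hit <- which(grepl(pat, em$channels$marker, ignore.case = TRUE))
    if (length(hit) == 0) {
      hit <- which(grepl(pat, em$channels$short_name, ignore.case = TRUE))
    }
    if (length(hit) > 1) {
      stop_cd26(sprintf("marker %s matches several channels (%s)",
                        marker, paste(hit, collapse = ", ")),
                class = "cd26_panel_error")
    }
    if (length(hit) == 1) em$channels$index[hit] else NA_integer_
  }
  idx <- vapply(PANEL_MARKERS, find_one, integer(1))
  if (anyNA(idx)) {
    stop_cd26(paste0("panel markers not found in channel metadata: ",
                     paste(PANEL_MARKERS[is.na(idx)], collapse = ", ")),
              class = "cd26_panel_error")
  }
  if (anyDuplicated(idx)) {
    stop_cd26("two panel markers resolved to the same channel",
              class = "cd26_panel_error")
  }
  idx
}
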