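#' @name fcsio
#' @title FCS 3.1 reading and writing for list-mode float data
#' @description
#' A bit-exact writer and reader for the subset of the Flow Cytometry
#' Standard 3.1 this package emits: single-dataset files, list mode
#' (`$MODE L`), float32 (`$DATATYPE F`, `$PnB 32`, `$PnE 0,0`), little-endian
#' by default.  The reader additionally accepts big-endian files and
#' `$DATATYPE D` (float64).  Ground-truth labels travel in a CSV sidecar
#' rather than in an FCS channel so that clustering tools see only the event
#' data.
NULL

FCS_DELIM <- "/"

fcs_escape <- function(x) gsub(FCS_DELIM, paste0(FCS_DELIM, FCS_DELIM), x,
                               fixed = TRUE)

fcs_build_text <- function(kw) {
  paste0(FCS_DELIM,
         paste0(names(kw), FCS_DELIM, fcs_escape(unname(kw)), FCS_DELIM,
                collapse = ""))
}

#' Write a dataset as an FCS 3.1 file
#'
#' Emits a 58-byte HEADER (`"FCS3.1"`, four spaces, six 8-character ASCII
#' offsets), a primary TEXT segment delimited by `/` (values containing the
#' delimiter are escaped by doubling), and a DATA segment of little-endian
#' float32 values in row-major list mode.
#'
#' @param dataset a `labeled_dataset` (see [build_separation_dataset()]) or a
#'   numeric event matrix.
#' @param path output file path.
#' @param channel_names parameter short names (`$PnN`); default `"Ch1"`,
#'   `"Ch2"`, ...
#' @return the path, invisibly.
#' @export
write_fcs <- function(dataset, path, channel_names = NULL) {
  events <- if (inherits(dataset, "labeled_dataset")) dataset$events
            else as.matrix(dataset)
  storage.mode(events) <- "double"
  if (!all(is.finite(events)))
    cb_stop("invalid_data", "events contain NaN or Inf")
  n <- nrow(events); p <- ncol(events)
  if (is.null(channel_names)) channel_names <- paste0("Ch", seq_len(p))
  stopifnot(length(channel_names) == p)

  base_kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
               "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0")
  tail_kw <- c("$NEXTDATA" = "0", "$MODE" = "L", "$DATATYPE" = "F",
               "$BYTEORD" = "1,2,3,4", "$PAR" = as.character(p),
               "$TOT" = as.character(n))
  for (j in seq_len(p)) {
    tail_kw[[sprintf("$P%dN", j)]] <- channel_names[j]
    tail_kw[[sprintf("$P%dB", j)]] <- "32"
    tail_kw[[sprintf("$P%dE", j)]] <- "0,0"
    tail_kw[[sprintf("$P%dR", j)]] <- as.character(ceiling(max(abs(events[, j])) + 1))
  }
  nbytes <- 4 * n * p
  # TEXT length depends on the printed data offsets; iterate to a fixed point
  data_begin <- 0; data_end <- 0
  for (i in 1:10) {
    kw <- c(base_kw, "$BEGINDATA" = as.character(data_begin),
            "$ENDDATA" = as.character(data_end), tail_kw)
    text <- fcs_build_text(kw)
    db <- 58L + nchar(text, type = "bytes")
    de <- db + nbytes - 1L
    if (db == data_begin && de == data_end) break
    data_begin <- db; data_end <- de
  }
  text_begin <- 58L
  text_end <- text_begin + nchar(text, type = "bytes") - 1L
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end,
                    if (data_end <= 99999999) data_begin else 0L,
                    if (data_end <= 99999999) data_end else 0L,
                    0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(events)), con, size = 4L, endian = "little")
  invisible(path)
}

fcs_parse_text <- function(raw_text) {
  s <- rawToChar(raw_text)
  delim <- substr(s, 1L, 1L)
  body <- substr(s, 2L, nchar(s))
  # strip the final delimiter; splitting keeps interior empties (escapes)
  if (substr(body, nchar(body), nchar(body)) == delim)
    body <- substr(body, 1L, nchar(body) - 1L)
  fields <- strsplit(body, delim, fixed = TRUE)[[1L]]
  # re-join empty fields produced by doubled (escaped) delimiters
  tokens <- character(0); buf <- fields[1L]; i <- 2L
  while (i <= length(fields)) {
    if (identical(fields[i], "")) {
      nxt <- if (i + 1L <= length(fields)) fields[i + 1L] else ""
      buf <- paste0(buf, delim, nxt)
      i <- i + 2L
    } else {
      tokens <- c(tokens, buf)
      buf <- fields[i]
      i <- i + 1L
    }
  }
  tokens <- c(tokens, buf)
  if (length(tokens) %% 2L != 0L)
    cb_stop("format_error", "TEXT segment has an odd number of fields")
  kw <- tokens[seq(2L, length(tokens), by = 2L)]
  names(kw) <- tokens[seq(1L, length(tokens), by = 2L)]
  kw
}

#' Read an FCS file written by this package (or compatible)
#'
#' Parses the HEADER offsets, the primary TEXT segment (delimiter escaping by
#' doubling is honoured) and the DATA segment according to `$DATATYPE`
#' (`F` or `D`), `$BYTEORD` (`1,2,3,4` or `4,3,2,1`) and `$PnB`.
#'
#' @param path FCS file path.
#' @return object of class `fcs_document`: list with `version`,
#'   `text_keywords` (named character vector in file order) and `data`
#'   (event matrix).
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) cb_stop("invalid_argument", "no such file: %s", path)
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 58L)
    cb_stop("format_error", "file shorter than the 58-byte FCS header")
  version <- rawToChar(bytes[1:6])
  if (!grepl("^FCS3\\.", version))
    cb_stop("format_error", "unsupported FCS version string '%s'", version)
  offs <- suppressWarnings(as.integer(vapply(0:5, function(i) {
    trimws(rawToChar(bytes[(11L + 8L * i):(18L + 8L * i)]))
  }, character(1))))
  if (anyNA(offs))
    cb_stop("format_error", "header offsets are not ASCII integers")
  tb <- offs[1]; te <- offs[2]
  if (tb < 58L || te < tb || te + 1L > length(bytes))
    cb_stop("format_error", "TEXT segment offsets outside the file")
  kw <- fcs_parse_text(bytes[(tb + 1L):(te + 1L)])

  need <- function(key) {
    if (!key %in% names(kw))
      cb_stop("format_error", "required keyword %s missing", key)
    unname(kw[[key]])
  }
  datatype <- need("$DATATYPE")
  if (!datatype %in% c("F", "D"))
    cb_stop("unsupported_feature", "only $DATATYPE F and D are supported, got %s",
            datatype)
  byteord <- need("$BYTEORD")
  endian <- switch(byteord, "1,2,3,4" = "little", "4,3,2,1" = "big",
                   cb_stop("unsupported_feature", "unsupported $BYTEORD %s",
                           byteord))
  p <- as.integer(need("$PAR")); n <- as.integer(need("$TOT"))
  size <- if (datatype == "F") 4L else 8L
  pnb <- vapply(seq_len(p), function(j) {
    v <- kw[sprintf("$P%dB", j)]
    if (is.na(v)) "" else unname(v)
  }, character(1))
  if (any(pnb != as.character(size * 8L)))
    cb_stop("format_error", "$PnB must be %d for $DATATYPE %s", size * 8L,
            datatype)
  db <- as.integer(need("$BEGINDATA")); de <- as.integer(need("$ENDDATA"))
  if (db == 0L) { db <- offs[3]; de <- offs[4] }
  expected <- as.double(n) * p * size
  if (de - db + 1L < expected || de + 1L > length(bytes))
    cb_stop("format_error",
            "DATA segment truncated: need %d bytes, segment has %d",
            expected, max(0L, min(de, length(bytes) - 1L) - db + 1L))
  vals <- readBin(bytes[(db + 1L):(de + 1L)], "double", n = n * p,
                  size = size, endian = endian)
  data <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  colnames(data) <- vapply(seq_len(p), function(j) {
    v <- kw[sprintf("$P%dN", j)]
    if (is.na(v)) paste0("Ch", j) else unname(v)
  }, character(1))
  structure(list(version = version, text_keywords = kw, data = data),
            class = "fcs_document")
}

#' @export
print.fcs_document <- function(x, ...) {
  cat(sprintf("<%s> %s events x %s parameters (%s)\n", x$version,
              x$text_keywords[["$TOT"]], x$text_keywords[["$PAR"]],
              paste(colnames(x$data), collapse = ", ")))
  invisible(x)
}

#' Ground-truth label sidecar I/O
#'
#' Labels are stored next to each FCS file as a two-column CSV
#' (`event_index,label`) with 0-based `event_index` matching the binary data
#' row order.
#'
#' @param labels integer ground-truth labels, one per event.
#' @param path sidecar CSV path.
#' @return `write_labels` the path invisibly; `read_labels` an integer label
#'   vector with attribute `event_index`.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(event_index = seq_along(labels) - 1L,
                   label = as.integer(labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df), c("event_index", "label")))
    cb_stop("format_error", "label sidecar must have columns event_index,label")
  structure(as.integer(df$label), event_index = as.integer(df$event_index))
}

#' Validate a label sidecar against its paired FCS file
#'
#' Checks row count and that `event_index` is exactly `0..n-1` in order.
#'
#' @param labels result of [read_labels()].
#' @param n_events event count of the paired FCS file.
#' @return `TRUE` invisibly; signals a consistency error otherwise.
#' @export
validate_labels <- function(labels, n_events) {
  idx <- attr(labels, "event_index")
  if (length(labels) != n_events)
    cb_stop("consistency_error", "sidecar has %d rows but FCS has %d events",
            length(labels), n_events)
  if (!identical(idx, seq_len(n_events) - 1L))
    cb_stop("consistency_error",
            "event_index is not the contiguous 0-based sequence")
  invisible(TRUE)
}
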