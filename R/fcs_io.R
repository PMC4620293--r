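#' Construct a sample_events object
#'
#' An event-level cytometry sample: one staining tube for one subject.
#' Intensities are linear arbitrary units on the 0--10,000 scale.
#'
#' @param events Numeric matrix, rows = events, columns = channels.
#' @param channels Data frame with columns `channel_id`, `fluorochrome`,
#'   `marker` (one row per column of `events`), or a character vector of
#'   channel ids (fluorochrome/marker then default to `"none"`).
#' @param subject_id,tube_id Opaque identifier strings.
#' @param validate Check invariants (range, uniqueness)? Default `TRUE`.
#' @return An object of class `sample_events`: a list with elements
#'   `subject_id`, `tube_id`, `channels` and `events`.
#' @examples
#' m <- matrix(runif(12, 0, 100), nrow = 4,
#'             dimnames = list(NULL, c("FSC", "SSC", "FL1")))
#' s <- sample_events(m, colnames(m), subject_id = "s1", tube_id = "t1")
#' s
#' @export
sample_events <- function(events, channels = colnames(events),
                          subject_id = "unknown", tube_id = "unknown",
                          validate = TRUE) {
  events <- as.matrix(events)
  storage.mode(events) <- "double"
  if (is.character(channels)) {
    channels <- data.frame(channel_id = channels,
                           fluorochrome = "none",
                           marker = "none",
                           stringsAsFactors = FALSE)
  }
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  stopifnot(all(c("channel_id", "fluorochrome", "marker") %in% names(channels)))
  if (validate) {
    if (nrow(events) < 1L)
      stop("sample_events: at least one event is required", call. = FALSE)
    if (ncol(events) != nrow(channels))
      stop("sample_events: column count (", ncol(events),
           ") does not equal channel count (", nrow(channels), ")",
           call. = FALSE)
    if (anyDuplicated(channels$channel_id))
      stop("sample_events: duplicate channel_id within tube", call. = FALSE)
    if (any(!is.finite(events)) || any(events < 0) || any(events > 10000))
      stop("sample_events: intensities must lie in [0, 10000]", call. = FALSE)
    scatter <- channels$channel_id %in% c("FSC", "SSC")
    if (any(channels$fluorochrome == "none" & !scatter & channels$marker != "none"))
      stop("sample_events: fluorochrome 'none' is only valid for scatter channels",
           call. = FALSE)
  }
  colnames(events) <- channels$channel_id
  structure(list(subject_id = subject_id, tube_id = tube_id,
                 channels = channels, events = events),
            class = "sample_events")
}

#' @export
print.sample_events <- function(x, ...) {
  cat("<sample_events> subject", x$subject_id, "tube", x$tube_id, "\n")
  cat(" ", nrow(x$events), "events x", ncol(x$events), "channels\n")
  lab <- paste0(x$channels$channel_id,
                ifelse(x$channels$marker %in% c("none", ""), "",
                       paste0(" (", x$channels$marker, ")")))
  cat("  channels:", paste(lab, collapse = ", "), "\n")
  invisible(x)
}

#' Extract the intensity vector of one marker
#'
#' @param sample A [sample_events] object.
#' @param marker Marker (antigen) name; matched case-insensitively
#'   against the tube's channel metadata.
#' @return Numeric vector of intensities.
#' @export
marker_values <- function(sample, marker) {
  sample$events[, channel_for_marker(sample, marker)]
}

# Column index of the channel carrying a marker (exact, case-insensitive).
channel_for_marker <- function(sample, marker) {
  hit <- which(toupper(sample$channels$marker) == toupper(marker))
  if (length(hit) != 1L)
    stop("panel error: tube '", sample$tube_id, "' does not carry marker '",
         marker, "' on exactly one channel", call. = FALSE)
  hit
}

marker_values <- function(sample, marker) {
  sample$events[, channel_for_marker(sample, marker)]
}

## ---------------------------------------------------------------------------
## FCS binary format
##
## HEADER: 6-byte version, 4 spaces, six 8-byte right-justified ASCII offsets
## (text start/end, data start/end, analysis start/end). TEXT: delimited
## keyword-value pairs. DATA (mode L): events x parameters, row-major.
## Written files are FCS 3.1, $DATATYPE F (float32), little-endian.
## ---------------------------------------------------------------------------

fcs_pad8 <- function(n) formatC(n, width = 8, flag = " ")

#' Write an event-level sample to disk
#'
#' FCS output is FCS 3.1 list-mode with float32 data, linear 0--10,000
#' scaling (`$PnE 0,0`, `$PnR 10000`) and marker names in the `$PnS`
#' keyword. CSV output is a plain comma-separated table with one header
#' row of channel ids and one row per event.
#'
#' @param sample A [sample_events] object.
#' @param path Output file path.
#' @param format `"fcs"` or `"csv"`.
#' @return `path`, invisibly.
#' @seealso [read_events()]
#' @export
write_events <- function(sample, path, format = c("fcs", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(sample, "sample_events"))
  ev <- sample$events
  if (any(!is.finite(ev)) || any(ev < 0) || any(ev > 10000))
    stop("validation error: intensity outside [0, 10000]", call. = FALSE)
  if (format == "csv") {
    df <- as.data.frame(ev)
    colnames(df) <- sample$channels$channel_id
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  npar <- ncol(ev)
  ntot <- nrow(ev)
  delim <- "|"
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0",
          "$PAR", as.character(npar), "$TOT", as.character(ntot),
          "$SRC", sample$subject_id, "TUBENAME", sample$tube_id)
  for (i in seq_len(npar)) {
    kw <- c(kw,
            sprintf("$P%dN", i), sample$channels$channel_id[i],
            sprintf("$P%dS", i), sample$channels$marker[i],
            sprintf("$P%dF", i), sample$channels$fluorochrome[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), "10000")
  }
  text <- paste0(delim, paste(kw, collapse = delim), delim)
  # data offsets depend on text length; %BD%/%ED% placeholders are replaced
  # by fixed-width numbers so the length is stable
  text_len <- nchar(text) - nchar("%BD%") - nchar("%ED%") + 16L
  header_len <- 58L
  data_begin <- header_len + text_len
  data_end <- data_begin + 4L * npar * ntot - 1L
  text <- sub("%BD%", formatC(data_begin, width = 8, flag = "0"), text,
              fixed = TRUE)
  text <- sub("%ED%", formatC(data_end, width = 8, flag = "0"), text,
              fixed = TRUE)
  header <- paste0("FCS3.1    ",
                   fcs_pad8(header_len), fcs_pad8(header_len + text_len - 1L),
                   fcs_pad8(data_begin), fcs_pad8(data_end),
                   fcs_pad8(0), fcs_pad8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(ev)), con, size = 4L, endian = "little")
  invisible(path)
}

fcs_parse_text <- function(raw_text) {
  txt <- rawToChar(raw_text)
  delim <- substr(txt, 1L, 1L)
  body <- substr(txt, 2L, nchar(txt))
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  parts <- parts[nchar(parts) > 0L | seq_along(parts) %% 2L == 0L]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1L, length(parts), by = 2L)]))
  vals <- trimws(parts[seq(2L, length(parts), by = 2L)])
  stats::setNames(as.list(vals), keys)
}

read_fcs <- function(path, subject_id = NULL, tube_id = NULL) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1"))
    stop("format error at offset 0: not an FCS 2.0/3.0/3.1 file (header '",
         version, "')", call. = FALSE)
  off <- suppressWarnings(as.numeric(substring(
    header, 10L + 8L * (0:5) + 1L, 10L + 8L * (1:6))))
  if (any(is.na(off[1:2])))
    stop("format error at offset 10: unreadable TEXT segment offsets",
         call. = FALSE)
  if (off[2] >= size)
    stop("format error at offset ", off[2],
         ": file truncated before end of TEXT segment", call. = FALSE)
  seek(con, off[1])
  kw <- fcs_parse_text(readBin(con, "raw", n = off[2] - off[1] + 1L))
  kval <- function(key, default = NULL) {
    v <- kw[[toupper(key)]]
    if (is.null(v)) default else v
  }
  data_begin <- off[3]
  data_end <- off[4]
  if (is.na(data_begin) || data_begin == 0) {
    data_begin <- as.numeric(kval("$BEGINDATA"))
    data_end <- as.numeric(kval("$ENDDATA"))
  }
  if (is.na(data_begin) || is.na(data_end) || data_begin <= 0)
    stop("format error: DATA segment offsets missing", call. = FALSE)
  npar <- as.integer(kval("$PAR"))
  ntot <- as.integer(kval("$TOT"))
  dtype <- toupper(kval("$DATATYPE", "F"))
  mode <- toupper(kval("$MODE", "L"))
  if (mode != "L")
    stop("format error: only list-mode ($MODE L) files are supported",
         call. = FALSE)
  byteord <- kval("$BYTEORD", "1,2,3,4")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  if (!is.null(kval("$SPILLOVER")) || !is.null(kval("SPILL")))
    warning("spillover/compensation matrix present in '", basename(path),
            "' is ignored; intensities are read as stored", call. = FALSE)

  bits <- vapply(seq_len(npar), function(i)
    as.integer(kval(sprintf("$P%dB", i), "32")), integer(1))
  nvals <- npar * ntot
  bytes_needed <- sum(rep(bits / 8, ntot))
  if (data_begin + bytes_needed - 1 > size)
    stop("format error at offset ", size,
         ": file truncated before end of DATA segment (expected ",
         data_begin + bytes_needed - 1, " bytes)", call. = FALSE)
  seek(con, data_begin)
  if (dtype == "F") {
    vals <- readBin(con, "double", n = nvals, size = 4L, endian = endian)
  } else if (dtype == "D") {
    vals <- readBin(con, "double", n = nvals, size = 8L, endian = endian)
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1L)
      stop("format error: mixed $PnB widths for integer data are not supported",
           call. = FALSE)
    sz <- bits[1] / 8L
    vals <- readBin(con, "integer", n = nvals, size = sz,
                    signed = sz > 2L, endian = endian)
    vals <- as.double(vals)
    vals[vals < 0] <- vals[vals < 0] + 2^bits[1]  # unsigned 32-bit wrap
  } else {
    stop("format error: unsupported $DATATYPE '", dtype, "'", call. = FALSE)
  }
  ev <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)

  # per-channel decode: $PnE log amplification, then map onto 0-10,000
  for (i in seq_len(npar)) {
    pe <- kval(sprintf("$P%dE", i), "0,0")
    ef <- suppressWarnings(as.numeric(strsplit(pe, ",")[[1]]))
    pr <- as.numeric(kval(sprintf("$P%dR", i), "10000"))
    if (length(ef) == 2L && !any(is.na(ef)) && ef[1] > 0) {
      f2 <- if (ef[2] == 0) 1 else ef[2]
      ev[, i] <- f2 * 10^(ef[1] * ev[, i] / pr)
    } else if (is.finite(pr) && pr > 0 && pr != 10000) {
      ev[, i] <- ev[, i] * (10000 / pr)
    }
  }
  ev[ev < 0] <- 0
  ev[ev > 10000] <- 10000

  chan <- data.frame(
    channel_id = vapply(seq_len(npar), function(i)
      kval(sprintf("$P%dN", i), sprintf("P%d", i)), character(1)),
    fluorochrome = vapply(seq_len(npar), function(i)
      kval(sprintf("$P%dF", i), "none"), character(1)),
    marker = vapply(seq_len(npar), function(i)
      kval(sprintf("$P%dS", i), "none"), character(1)),
    stringsAsFactors = FALSE)
  sample_events(ev, chan,
                subject_id = subject_id %||% kval("$SRC", "unknown"),
                tube_id = tube_id %||% kval("TUBENAME", "unknown"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an event-level cytometry sample
#'
#' Reads FCS 2.0/3.0/3.1 list-mode files or a CSV with a header row of
#' channel ids, returning intensities on the linear 0--10,000 scale.
#' Marker names are taken from stain metadata (`$PnS`) when present,
#' otherwise from a sidecar panel configuration. Spillover matrices in
#' real files are ignored with a warning (data are treated as
#' compensated).
#'
#' @param path Path to an FCS or CSV file.
#' @param format_hint Optional `"fcs"` or `"csv"`; by default the format
#'   is detected from the file content.
#' @param panel Optional sidecar panel configuration: a named list (or
#'   path to a YAML/JSON file) mapping `tube_id` to a named list
#'   `channel_id -> marker`.
#' @param subject_id,tube_id Optional identifier overrides.
#' @return A [sample_events] object.
#' @export
read_events <- function(path, format_hint = NULL, panel = NULL,
                        subject_id = NULL, tube_id = NULL) {
  if (!file.exists(path))
    stop("format error: file '", path, "' does not exist", call. = FALSE)
  fmt <- format_hint
  if (is.null(fmt)) {
    head <- readChar(path, 3L, useBytes = TRUE)
    fmt <- if (identical(head, "FCS")) "fcs" else "csv"
  }
  s <- if (fmt == "fcs") {
    read_fcs(path, subject_id = subject_id, tube_id = tube_id)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    sample_events(as.matrix(df), colnames(df),
                  subject_id = subject_id %||% "unknown",
                  tube_id = tube_id %||% "unknown")
  }
  if (!is.null(panel)) {
    if (is.character(panel) && length(panel) == 1L)
      panel <- yaml::read_yaml(panel)
    tube_map <- panel[[s$tube_id]]
    if (!is.null(tube_map)) {
      unknown <- setdiff(names(tube_map), s$channels$channel_id)
      if (length(unknown))
        stop("metadata error: panel names unknown channel id(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      idx <- match(names(tube_map), s$channels$channel_id)
      s$channels$marker[idx] <- unlist(tube_map, use.names = FALSE)
    }
  }
  s
}

#' Validate an acquisition
#'
#' Checks a sample against acquisition requirements: a minimum event
#' count (default 2e5, the study's acquisition floor), the
#' 0--10,000 intensity range, and channel-id uniqueness. Findings are
#' reported, not thrown.
#'
#' @param sample A [sample_events] object.
#' @param min_events Minimum acceptable number of events.
#' @return A list of class `acquisition_report` with elements `pass`
#'   (logical), `n_events`, `count_deficit`, `range_violations`
#'   (number of out-of-range intensities) and `duplicate_channels`.
#' @export
validate_acquisition <- function(sample, min_events = 2e5) {
  stopifnot(inherits(sample, "sample_events"))
  n <- nrow(sample$events)
  deficit <- max(0, min_events - n)
  nrange <- sum(!is.finite(sample$events) | sample$events < 0 |
                  sample$events > 10000)
  dups <- unique(sample$channels$channel_id[duplicated(sample$channels$channel_id)])
  rep <- list(pass = deficit == 0 && nrange == 0 && length(dups) == 0L,
              n_events = n, min_events = min_events,
              count_deficit = deficit,
              range_violations = nrange,
              duplicate_channels = dups)
  class(rep) <- "acquisition_report"
  rep
}

#' @export
print.acquisition_report <- function(x, ...) {
  cat("<acquisition_report>", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  events:", x$n_events, "(minimum", x$min_events)
  if (x$count_deficit > 0) cat("; deficit", x$count_deficit)
  cat(")\n  range violations:", x$range_violations, "\n")
  if (length(x$duplicate_channels))
    cat("  duplicate channels:", paste(x$duplicate_channels, collapse = ", "),
        "\n")
  invisible(x)
}
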