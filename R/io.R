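# Standard-format I/O: raw container with JSON sidecar, EDF, hypnogram TSV,
# and the interval/event tables.

#' Read a multichannel recording from disk
#'
#' Two formats are supported:
#' \describe{
#'   \item{`container`}{a raw little-endian float matrix (time-major: all
#'     channels of sample 1, then sample 2, ...) with a JSON sidecar
#'     `<path>.json` holding `fs`, `channel_ids`, `modality`, `t0`, `dtype`
#'     and `shape`. Bit-exact, language-agnostic and trivial to parse.}
#'   \item{`edf`}{European Data Format (16-bit). All signals must share one
#'     sampling rate; EDF files with mixed per-signal rates are rejected.}
#' }
#'
#' @param path file path. For `container` this is the raw data file; the
#'   sidecar is `<path>.json`.
#' @param format `"container"` or `"edf"`; inferred from the `.edf` extension
#'   when missing.
#' @return a [recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "container", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "container"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         container = read_container(path),
         edf = read_edf(path))
}

#' Write a multichannel recording to disk
#'
#' @param rec a [recording()].
#' @param path destination path (for `container`, the sidecar `<path>.json`
#'   is written alongside).
#' @param format `"container"` or `"edf"` (inferred from extension when
#'   missing). Container round-trips exactly at the stored precision
#'   (`float64` by default); EDF quantizes to 16 bits over the per-channel
#'   physical range.
#' @param dtype container storage type, `"float64"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "container", "edf"),
                            dtype = c("float64", "float32")) {
  stopifnot(inherits(rec, "recording"))
  format <- match.arg(format)
  dtype <- match.arg(dtype)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "container"
  }
  switch(format,
         container = write_container(rec, path, dtype),
         edf = write_edf(rec, path))
  invisible(path)
}

container_sidecar <- function(path) paste0(path, ".json")

write_container <- function(rec, path, dtype = "float64") {
  size <- if (dtype == "float32") 4L else 8L
  meta <- list(format = "spindleloc-container", version = 1L,
               fs = rec$fs, channel_ids = rec$channel_ids,
               modality = rec$modality, t0 = rec$t0, dtype = dtype,
               shape = c(nrow(rec$data), ncol(rec$data)),
               layout = "time-major", endian = "little")
  jsonlite::write_json(meta, container_sidecar(path), auto_unbox = TRUE,
                       digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  # column-major vector of the channels x samples matrix = time-major stream
  writeBin(as.numeric(rec$data), con, size = size, endian = "little")
}

read_container <- function(path) {
  sidecar <- container_sidecar(path)
  if (!file.exists(sidecar)) stop("missing container sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$format, "spindleloc-container")) {
    stop("not a spindleloc container: ", path)
  }
  shape <- as.integer(meta$shape)
  size <- if (identical(meta$dtype, "float32")) 4L else 8L
  n <- prod(shape)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "double", n = n, size = size, endian = "little")
  if (length(v) != n) stop("container data truncated: ", path)
  recording(matrix(v, nrow = shape[1L]), fs = meta$fs,
            channel_ids = meta$channel_ids, modality = meta$modality,
            t0 = meta$t0 %||% 0)
}

# --- EDF ---------------------------------------------------------------------
# Minimal EDF (not EDF+) reader/writer: 256-byte fixed header, 256 bytes per
# signal (field-major), 16-bit little-endian samples in data records.

edf_num <- function(x, width = 8L) {
  s <- sprintf("%.10g", x)
  if (nchar(s) > width) s <- sprintf("%.*e", width - 7L, x)
  if (nchar(s) > width) stop("cannot encode ", x, " in ", width, " EDF chars")
  s
}

edf_pad <- function(s, width) {
  s <- substr(s, 1L, width)
  formatC(s, width = -width)  # left-justified, space padded
}

write_edf <- function(rec, path) {
  n <- ncol(rec$data)
  ns <- nrow(rec$data)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF output requires an integer sampling rate")
  fs <- as.integer(round(fs))
  if (n %% fs == 0L) {
    rec_dur <- 1
    nr <- fs
  } else {
    rec_dur <- n / fs
    nr <- n
  }
  n_rec <- as.integer(n / nr)
  # physical range: symmetric, encoded in ASCII first so that the scaling we
  # apply matches what a reader will parse back
  pr <- apply(abs(rec$data), 1L, max)
  pr[pr == 0] <- 1
  pmax_str <- vapply(pr * 1.0001, edf_num, "")
  pmax_num <- as.numeric(pmax_str)
  pmin_num <- -pmax_num
  dmin <- -32768
  dmax <- 32767
  hdr_bytes <- 256L + 256L * ns
  header <- paste0(
    edf_pad("0", 8L), edf_pad("synthetic", 80L), edf_pad("spindleloc", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(as.character(hdr_bytes), 8L), edf_pad("", 44L),
    edf_pad(as.character(n_rec), 8L), edf_pad(edf_num(rec_dur), 8L),
    edf_pad(as.character(ns), 4L))
  sig_hdr <- paste0(
    paste(vapply(rec$channel_ids, edf_pad, "", width = 16L), collapse = ""),
    paste(rep(edf_pad("", 80L), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8L), ns), collapse = ""),
    paste(vapply(pmin_num, function(v) edf_pad(edf_num(v), 8L), ""), collapse = ""),
    paste(vapply(pmax_num, function(v) edf_pad(edf_num(v), 8L), ""), collapse = ""),
    paste(rep(edf_pad(as.character(dmin), 8L), ns), collapse = ""),
    paste(rep(edf_pad(as.character(dmax), 8L), ns), collapse = ""),
    paste(rep(edf_pad("", 80L), ns), collapse = ""),
    paste(rep(edf_pad(as.character(nr), 8L), ns), collapse = ""),
    paste(rep(edf_pad("", 32L), ns), collapse = ""))
  dig <- round((rec$data - pmin_num) / (pmax_num - pmin_num) *
                 (dmax - dmin) + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  storage.mode(dig) <- "integer"
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(header, sig_hdr)), con)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * nr + 1L):(r * nr)
    # per record: all samples of signal 1, then signal 2, ...
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) rawToChar(readBin(con, "raw", n = nc))
  num <- function(nc) as.numeric(trimws(rd(nc)))
  rd(8L)                      # version
  rd(160L)                    # patient + recording id
  rd(16L)                     # date + time
  num(8L)                     # header bytes
  rd(44L)                     # reserved
  n_rec <- as.integer(num(8L))
  rec_dur <- num(8L)
  ns <- as.integer(num(4L))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header: ", path)
  fld <- function(width) {
    vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  }
  labels <- fld(16L)
  fld(80L)                    # transducer
  fld(8L)                     # physical dimension
  pmin <- as.numeric(fld(8L))
  pmax <- as.numeric(fld(8L))
  dmin <- as.numeric(fld(8L))
  dmax <- as.numeric(fld(8L))
  fld(80L)                    # prefiltering
  nr <- as.integer(fld(8L))
  fld(32L)                    # reserved
  if (anyNA(c(pmin, pmax, dmin, dmax, nr))) stop("unreadable EDF header: ", path)
  if (length(unique(nr)) != 1L) {
    stop("EDF signals with unequal sampling rates are not supported")
  }
  nr <- nr[1L]
  fs <- nr / rec_dur
  out <- matrix(0, nrow = ns, ncol = nr * n_rec)
  for (r in seq_len(n_rec)) {
    d <- readBin(con, "integer", n = nr * ns, size = 2L, signed = TRUE,
                 endian = "little")
    if (length(d) != nr * ns) stop("EDF data truncated: ", path)
    blk <- matrix(d, nrow = nr)  # columns = signals
    cols <- ((r - 1L) * nr + 1L):(r * nr)
    out[, cols] <- t(blk * rep((pmax - pmin) / (dmax - dmin), each = nr) +
                       rep(pmin - dmin * (pmax - pmin) / (dmax - dmin), each = nr))
  }
  if (anyDuplicated(labels)) labels <- make.unique(labels, sep = "_")
  recording(out, fs = fs, channel_ids = labels, modality = "eeg-sensor")
}

# --- hypnogram TSV -----------------------------------------------------------

#' Read a hypnogram from TSV
#'
#' Accepts two or three tab-separated columns: `epoch_index`, `stage`, and an
#' optional `artifact` flag (0/1). A header line is detected automatically.
#'
#' @param path TSV file.
#' @param epoch_s epoch duration in seconds (default 30).
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_s = 30) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty hypnogram file: ", path)
  first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  has_header <- length(first) >= 2L && !toupper(trimws(first[2L])) %in% SLEEP_STAGES
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("hypnogram TSV needs >= 2 columns")
  ord <- order(as.integer(tab[[1L]]))
  stages <- tab[[2L]][ord]
  artifact <- if (ncol(tab) >= 3L) as.integer(tab[[3L]][ord]) == 1L else NULL
  hypnogram(stages, artifact, epoch_s = epoch_s)
}

#' Write a hypnogram to TSV
#'
#' @param hyp a [hypnogram()].
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  tab <- data.frame(epoch_index = seq_along(hyp$stages), stage = hyp$stages,
                    artifact = as.integer(hyp$artifact))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- interval / event tables -------------------------------------------------

#' Read/write spindle interval tables
#'
#' Per-channel spindle detections as TSV with columns `channel_id`,
#' `start_s`, `end_s`, `peak_s`, `peak_amp`, `duration_s`, ordered by
#' `(channel_id, start_s)`.
#'
#' @param intervals data.frame of detections as produced by
#'   [detect_recording()].
#' @param path TSV file path.
#' @return `read_intervals` returns the data.frame; `write_intervals` returns
#'   `path` invisibly.
#' @export
write_intervals <- function(intervals, path) {
  intervals <- intervals[order(intervals$channel_id, intervals$start_s), ,
                         drop = FALSE]
  utils::write.table(intervals, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(channel_id = "character"))
}

#' Read/write spindle event tables
#'
#' Cross-channel spindle events as TSV with columns `event_id`, `center_s`,
#' `start_s`, `end_s`, `extent`, `n_channels_total`, `channels`
#' (semicolon-joined contributing channel ids) and `seam_crossing`.
#'
#' @param events data.frame of events as produced by [find_events()].
#' @param path TSV file path.
#' @return `read_events` returns the data.frame; `write_events` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(channels = "character"))
}
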