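#' Multichannel recording
#'
#' Container for a multichannel electrophysiological time series: a channels
#' x samples matrix with a sampling rate, ordered channel identifiers and a
#' free-form modality tag (e.g. `"eeg-sensor"`, `"source-eeg"`,
#' `"source-meg"`, `"source-combined"`). Signal units are arbitrary but must
#' be uniform within a channel.
#'
#' @param data numeric matrix, channels x samples; all values finite.
#' @param fs sampling rate in Hz, positive.
#' @param channel_ids character vector of distinct channel labels, one per
#'   row of `data`. Defaults to the rownames of `data`, or `ch001 ...` if
#'   absent.
#' @param modality free-form tag describing the acquisition/reconstruction
#'   space.
#' @param t0 start-time offset in seconds (default 0).
#' @return an object of class `"recording"`.
#' @examples
#' rec <- recording(matrix(rnorm(400), nrow = 2), fs = 200)
#' n_samples(rec)
#' duration_s(rec)
#' @export
recording <- function(data, fs, channel_ids = NULL, modality = "eeg-sensor",
                      t0 = 0) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix (channels x samples)")
  }
  if (nrow(data) < 1L) stop("recording must have at least one channel")
  if (!all(is.finite(data))) stop("all sample values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)")
  }
  if (is.null(channel_ids)) {
    channel_ids <- rownames(data) %||% sprintf("ch%03d", seq_len(nrow(data)))
  }
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(data)) {
    stop("`channel_ids` must have one entry per channel")
  }
  if (anyDuplicated(channel_ids)) stop("channel_ids must be distinct")
  rownames(data) <- channel_ids
  structure(
    list(data = data, fs = fs, channel_ids = channel_ids,
         modality = as.character(modality)[1L], t0 = as.numeric(t0)[1L]),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s), modality '%s'\n",
              nrow(x$data), ncol(x$data), x$fs, duration_s(x), x$modality))
  invisible(x)
}

#' @rdname recording
#' @param rec a `recording`.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname recording
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Sleep-stage hypnogram
#'
#' Ordered per-epoch sleep-stage labels with artifact flags. Epochs are
#' `epoch_s` seconds long (30 s by standard scoring) and are aligned to the
#' recording start.
#'
#' @param stages character vector of stage labels, each one of
#'   `WAKE`, `REM`, `N1`, `N2`, `N3`.
#' @param artifact logical vector of per-epoch artifact flags, same length as
#'   `stages` (default all `FALSE`).
#' @param epoch_s epoch duration in seconds (default 30).
#' @return an object of class `"hypnogram"`.
#' @examples
#' hyp <- hypnogram(c("WAKE", "N1", "N2", "N2", "N3", "N2"))
#' @export
hypnogram <- function(stages, artifact = NULL, epoch_s = 30) {
  stages <- toupper(as.character(stages))
  bad <- setdiff(unique(stages), SLEEP_STAGES)
  if (length(bad)) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(artifact)) artifact <- rep(FALSE, length(stages))
  artifact <- as.logical(artifact)
  if (length(artifact) != length(stages)) {
    stop("`stages` and `artifact` must have equal length")
  }
  if (anyNA(artifact)) stop("artifact flags must be TRUE/FALSE")
  if (!is.numeric(epoch_s) || epoch_s <= 0) stop("`epoch_s` must be positive")
  structure(list(epoch_s = as.numeric(epoch_s), stages = stages,
                 artifact = artifact),
            class = "hypnogram")
}

#' Recognized sleep-stage labels
#' @export
SLEEP_STAGES <- c("WAKE", "REM", "N1", "N2", "N3")

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = SLEEP_STAGES))
  cat(sprintf("<hypnogram> %d x %g s epochs (%d artifact): %s\n",
              length(x$stages), x$epoch_s, sum(x$artifact),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Half-open time interval
#'
#' Intervals are half-open `[start_s, end_s)` in seconds throughout the
#' package.
#'
#' @param start_s,end_s numeric vectors (seconds), `0 <= start_s < end_s`.
#' @return a data.frame with columns `start_s`, `end_s`.
#' @export
sample_interval <- function(start_s, end_s) {
  start_s <- as.numeric(start_s)
  end_s <- as.numeric(end_s)
  if (any(start_s < 0) || any(start_s >= end_s)) {
    stop("intervals must satisfy 0 <= start_s < end_s")
  }
  data.frame(start_s = start_s, end_s = end_s)
}

#' Extract all epochs of one sleep stage
#'
#' Selects every non-artifact epoch scored as `stage`, concatenates the
#' corresponding samples in temporal order, and returns both the concatenated
#' recording and the source intervals in the original recording's time. The
#' trailing part of the recording not filling a whole epoch is ignored.
#'
#' @param rec a [recording()].
#' @param hyp a [hypnogram()] covering the recording duration.
#' @param stage stage label to extract (default `"N2"`, where spindles
#'   predominate).
#' @return list with elements `recording` (the stage-restricted recording,
#'   `t0 = 0`) and `intervals` (data.frame of half-open source intervals in
#'   original time, including `t0`).
#' @examples
#' rec <- recording(matrix(rnorm(2 * 200 * 180), nrow = 2), fs = 200)
#' hyp <- hypnogram(c("WAKE", "N1", "N2", "N2", "N3", "N2"))
#' n2 <- extract_stage(rec, hyp, "N2")
#' duration_s(n2$recording)  # 90 s
#' @export
extract_stage <- function(rec, hyp, stage = "N2") {
  stopifnot(inherits(rec, "recording"), inherits(hyp, "hypnogram"))
  stage <- toupper(stage)
  if (!stage %in% SLEEP_STAGES) stop("unknown stage label: ", stage)
  ep_n <- as.integer(floor(hyp$epoch_s * rec$fs))
  n_ep_rec <- n_samples(rec) %/% ep_n
  if (n_ep_rec > length(hyp$stages)) {
    stop("hypnogram does not cover the recording duration")
  }
  sel <- which(hyp$stages[seq_len(n_ep_rec)] == stage &
                 !hyp$artifact[seq_len(n_ep_rec)])
  if (!length(sel)) {
    stop(sprintf("no non-artifact '%s' epochs in the hypnogram", stage))
  }
  cols <- unlist(lapply(sel, function(e) ((e - 1L) * ep_n + 1L):(e * ep_n)))
  out <- recording(rec$data[, cols, drop = FALSE], fs = rec$fs,
                   channel_ids = rec$channel_ids, modality = rec$modality,
                   t0 = 0)
  ints <- sample_interval(rec$t0 + (sel - 1L) * hyp$epoch_s,
                          rec$t0 + sel * hyp$epoch_s)
  list(recording = out, intervals = ints)
}

#' Concatenation seams of a stage-restricted recording
#'
#' Times (in concatenated time) at which two selected epochs were not
#' contiguous in the original recording. Event windows crossing a seam are
#' flagged by [find_events()].
#'
#' @param intervals the `intervals` component returned by [extract_stage()].
#' @param epoch_s epoch duration in seconds.
#' @return numeric vector of seam times in seconds (possibly empty).
#' @export
stage_seams <- function(intervals, epoch_s = 30) {
  if (nrow(intervals) < 2L) return(numeric(0))
  gap <- intervals$start_s[-1L] != intervals$end_s[-nrow(intervals)]
  epoch_s * which(gap)
}
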