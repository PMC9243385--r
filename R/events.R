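# Aggregation of per-channel spindle intervals into cross-channel spindle
# events: binary detection matrix, smoothed aggregate count, local maxima
# with minimum separation and extent floor, 1 s event windows.

#' Event-builder configuration
#'
#' @param smooth_s moving-average window (seconds) applied to the aggregate
#'   channel-count signal (default 0.5).
#' @param min_peak_dist_s minimum distance between event maxima in seconds
#'   (default 0.5).
#' @param min_extent_frac minimum spatial extent as a fraction of the number
#'   of channels (default 0.01); the floor is `ceiling(frac * n_channels)`
#'   channels.
#' @param window_s event window length in seconds (default 1).
#' @return an object of class `"event_config"`.
#' @export
event_config <- function(smooth_s = 0.5, min_peak_dist_s = 0.5,
                         min_extent_frac = 0.01, window_s = 1.0) {
  if (smooth_s <= 0 || min_peak_dist_s <= 0 || window_s <= 0) {
    stop("smooth_s, min_peak_dist_s and window_s must be positive")
  }
  if (!(min_extent_frac > 0 && min_extent_frac <= 1)) {
    stop("min_extent_frac must be in (0, 1]")
  }
  structure(list(smooth_s = smooth_s, min_peak_dist_s = min_peak_dist_s,
                 min_extent_frac = min_extent_frac, window_s = window_s),
            class = "event_config")
}

#' Binary detection matrix from per-channel intervals
#'
#' `y[c, t] = 1` exactly for the samples falling inside any detected spindle
#' interval of channel `c` (half-open intervals); overlapping intervals on a
#' channel contribute a single run of ones.
#'
#' @param intervals data.frame with columns `channel_id`, `start_s`, `end_s`
#'   (e.g. from [detect_recording()]); every `channel_id` must appear in
#'   `channel_ids`.
#' @param channel_ids full ordered set of channel labels (rows of the
#'   output).
#' @param fs sampling rate in Hz.
#' @param n_samples number of samples (columns of the output).
#' @return object of class `"detection_matrix"`: list with binary matrix
#'   `y`, `fs` and `channel_ids`.
#' @export
build_detection_matrix <- function(intervals, channel_ids, fs, n_samples) {
  unknown <- setdiff(unique(intervals$channel_id), channel_ids)
  if (length(unknown)) {
    stop("intervals reference unknown channel(s): ",
         paste(unknown, collapse = ", "))
  }
  y <- matrix(0L, nrow = length(channel_ids), ncol = n_samples,
              dimnames = list(channel_ids, NULL))
  if (nrow(intervals)) {
    row_of <- match(intervals$channel_id, channel_ids)
    for (i in seq_len(nrow(intervals))) {
      rg <- interval_to_samples(intervals$start_s[i], intervals$end_s[i],
                                fs, n_samples)
      if (rg[1L] <= rg[2L]) y[row_of[i], rg[1L]:rg[2L]] <- 1L
    }
  }
  structure(list(y = y, fs = fs, channel_ids = channel_ids),
            class = "detection_matrix")
}

#' Aggregate detection counts across channels
#'
#' Sums the binary detection matrix across channels into the aggregate
#' signal `Y_raw` (number of channels with a spindle at each sample) and
#' smooths it with a centered `smooth_s` moving average (edge-truncated)
#' into `Y_smooth`.
#'
#' @param dm a [build_detection_matrix()] result.
#' @param cfg an [event_config()].
#' @return object of class `"aggregate_signal"`: list with `Y_raw`
#'   (integer), `Y_smooth` (numeric) and `fs`.
#' @export
aggregate_detections <- function(dm, cfg = event_config()) {
  stopifnot(inherits(dm, "detection_matrix"))
  y_raw <- as.integer(colSums(dm$y))
  y_smooth <- moving_average(y_raw, odd_window(cfg$smooth_s, dm$fs))
  structure(list(Y_raw = y_raw, Y_smooth = y_smooth, fs = dm$fs),
            class = "aggregate_signal")
}

# Local maxima of a series, plateau-aware: a peak is a maximal run of equal
# values strictly greater than both neighboring values; its location is the
# plateau's center sample. Runs touching the series ends are not peaks.
# Returns 1-based indices.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  mid <- 2L:(k - 1L)
  is_pk <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  idx <- mid[is_pk]
  starts[idx] + (r$lengths[idx] - 1L) %/% 2L
}

# Minimum-distance suppression of peaks, highest first; exact ties keep the
# earlier peak. Peaks closer than min_dist samples to an already kept,
# higher peak are dropped.
suppress_peaks <- function(idx, height, min_dist) {
  if (!length(idx)) return(integer(0))
  ord <- order(-height, idx)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(idx[i] - kept) >= min_dist)) {
      kept <- c(kept, idx[i])
    }
  }
  sort(kept)
}

#' Discrete spindle events from the aggregate signal
#'
#' Detects temporal local maxima of the smoothed aggregate `Y_smooth` with a
#' minimum separation of `min_peak_dist_s` (when two maxima compete, the
#' higher wins; exact ties keep the earlier). Maxima whose smoothed height
#' falls below `ceiling(min_extent_frac * n_channels)` are discarded as
#' spurious: applying the floor to the smoothed height (the series the
#' maxima live on) suppresses isolated short single-channel detections,
#' which would otherwise turn every noise run on one channel into an event.
#' Each surviving maximum defines a `window_s` window centered on it
#' (clipped at the record edges); the spatial extent of the event is the
#' maximum of the raw aggregate `Y_raw` inside the window, i.e. the peak
#' number of simultaneously detecting channels.
#'
#' If `seams` (concatenation boundaries between non-contiguous sleep epochs,
#' see [stage_seams()]) are supplied, events whose window crosses a seam are
#' flagged and their extent and channel set are computed only over the
#' seam-bounded segment containing the event center.
#'
#' @param agg an [aggregate_detections()] result.
#' @param dm the [build_detection_matrix()] the aggregate came from (used
#'   for the contributing-channel sets and the channel count).
#' @param cfg an [event_config()].
#' @param seams numeric vector of seam times in seconds (default none).
#' @return data.frame with columns `event_id`, `center_s`, `start_s`,
#'   `end_s`, `extent`, `n_channels_total`, `channels` (semicolon-joined ids
#'   of channels detecting anywhere in the window) and `seam_crossing`.
#' @export
find_events <- function(agg, dm, cfg = event_config(), seams = numeric(0)) {
  stopifnot(inherits(agg, "aggregate_signal"), inherits(dm, "detection_matrix"))
  fs <- agg$fs
  n <- length(agg$Y_raw)
  n_ch <- length(dm$channel_ids)
  empty <- data.frame(event_id = integer(0), center_s = numeric(0),
                      start_s = numeric(0), end_s = numeric(0),
                      extent = integer(0), n_channels_total = integer(0),
                      channels = character(0), seam_crossing = logical(0))
  pk <- local_maxima(agg$Y_smooth)
  pk <- pk[agg$Y_smooth[pk] > 0]
  if (!length(pk)) return(empty)
  pk <- suppress_peaks(pk, agg$Y_smooth[pk],
                       min_dist = cfg$min_peak_dist_s * fs)
  floor_ext <- as.integer(ceiling(cfg$min_extent_frac * n_ch))
  pk <- pk[agg$Y_smooth[pk] >= floor_ext - 1e-9]
  if (!length(pk)) return(empty)
  seg_edges <- sort(unique(c(0, seams, n / fs)))
  rows <- lapply(pk, function(p) {
    center_s <- (p - 1L) / fs
    w0 <- max(0, center_s - cfg$window_s / 2)
    w1 <- min(n / fs, center_s + cfg$window_s / 2)
    crossing <- any(seams > w0 & seams < w1)
    seg <- findInterval(center_s, seg_edges, rightmost.closed = TRUE)
    s0 <- max(w0, seg_edges[seg])
    s1 <- min(w1, seg_edges[seg + 1L])
    rg <- interval_to_samples(s0, s1, fs, n)
    cols <- rg[1L]:rg[2L]
    extent <- max(agg$Y_raw[cols])
    act <- rowSums(dm$y[, cols, drop = FALSE]) > 0
    data.frame(center_s = center_s, start_s = w0, end_s = w1,
               extent = as.integer(extent), n_channels_total = n_ch,
               channels = paste(dm$channel_ids[act], collapse = ";"),
               seam_crossing = crossing)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$center_s), , drop = FALSE]
  cbind(event_id = seq_len(nrow(out)), out)
}

#' Build spindle events directly from interval detections
#'
#' Convenience wrapper chaining [build_detection_matrix()],
#' [aggregate_detections()] and [find_events()].
#'
#' @inheritParams build_detection_matrix
#' @inheritParams find_events
#' @return data.frame of events (see [find_events()]).
#' @export
build_events <- function(intervals, channel_ids, fs, n_samples,
                         cfg = event_config(), seams = numeric(0)) {
  dm <- build_detection_matrix(intervals, channel_ids, fs, n_samples)
  agg <- aggregate_detections(dm, cfg)
  find_events(agg, dm, cfg, seams)
}

#' Spindle event density
#'
#' Events per minute of analyzed sleep, normalizing counts for different
#' sleep durations.
#'
#' @param events data.frame of events (see [find_events()]) or an event
#'   count.
#' @param analyzed_duration_s analyzed duration in seconds, positive.
#' @return events per minute.
#' @examples
#' event_density(data.frame(event_id = 1:20), 120)  # 10 per minute
#' @export
event_density <- function(events, analyzed_duration_s) {
  if (!is.numeric(analyzed_duration_s) || analyzed_duration_s <= 0) {
    stop("analyzed_duration_s must be positive")
  }
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  n / (analyzed_duration_s / 60)
}
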