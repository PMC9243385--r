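# Band-pass filtering and resampling of recordings.

# Zero-phase band-pass of one channel: forward-backward Butterworth
# high-pass (order 2) and low-pass (order 4) applied in cascade. Separate
# sections keep the filter numerically stable for very low cutoffs (e.g.
# 0.3 Hz at a 600 Hz rate); the steeper low-pass gives > 20 dB rejection
# one octave above a 35 Hz edge.
bandpass_channel <- function(x, fs, lo, hi) {
  nyq <- fs / 2
  blo <- signal::butter(4, hi / nyq, type = "low")
  bhi <- signal::butter(2, lo / nyq, type = "high")
  y <- signal::filtfilt(blo, x)
  as.numeric(signal::filtfilt(bhi, y))
}

# Narrow pass-band (e.g. the spindle band) in one section.
narrowband_channel <- function(x, fs, lo, hi) {
  b <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

#' Band-pass filter and resample a recording
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass to every
#' channel, then resamples to `fs_out`. Zero-phase application avoids latency
#' bias in spindle timing. When `fs / fs_out` is an integer the band-limited
#' signal is decimated directly (the pass-band upper edge must lie below the
#' output Nyquist, so no aliasing is introduced); otherwise samples are
#' linearly interpolated onto the output grid.
#'
#' @param rec a [recording()].
#' @param band_lo,band_hi pass-band edges in Hz (defaults 0.3 and 35).
#' @param fs_out output sampling rate in Hz (default 200). Must satisfy
#'   `0 < band_lo < band_hi < fs_out / 2 <= fs / 2`.
#' @return a [recording()] at `fs_out` with channel order preserved.
#' @examples
#' rec <- recording(matrix(sin(2 * pi * 10 * (0:5999) / 600), nrow = 1),
#'                  fs = 600)
#' out <- preprocess(rec)  # 10 Hz sine at 200 Hz
#' @export
preprocess <- function(rec, band_lo = 0.3, band_hi = 35, fs_out = 200) {
  stopifnot(inherits(rec, "recording"))
  if (!(band_lo > 0 && band_lo < band_hi && band_hi < fs_out / 2 &&
        fs_out <= rec$fs)) {
    stop("require 0 < band_lo < band_hi < fs_out/2 <= fs/2")
  }
  filt <- t(apply(rec$data, 1L, bandpass_channel, fs = rec$fs,
                  lo = band_lo, hi = band_hi))
  if (abs(rec$fs / fs_out - round(rec$fs / fs_out)) < 1e-9) {
    step <- as.integer(round(rec$fs / fs_out))
    out <- filt[, seq(1L, ncol(filt), by = step), drop = FALSE]
  } else {
    t_in <- (seq_len(ncol(filt)) - 1L) / rec$fs
    t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
    out <- t(apply(filt, 1L, function(ch) {
      stats::approx(t_in, ch, xout = t_out)$y
    }))
  }
  recording(out, fs = fs_out, channel_ids = rec$channel_ids,
            modality = rec$modality, t0 = rec$t0)
}
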