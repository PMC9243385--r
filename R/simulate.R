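# Synthetic nap-like recordings with known ground-truth spindle bursts:
# 1/f background noise plus Hanning-windowed sigma-band bursts whose
# amplitudes are parameterized relative to each channel's background
# sigma-band RMS.

#' Ground-truth specification for a synthetic recording
#'
#' @param bursts data.frame with columns `onset_s`, `duration_s`, `freq_hz`,
#'   `amplitude_mult` (burst envelope peak as a multiple of the channel's
#'   background sigma-band RMS) and `channels` (semicolon-joined channel
#'   ids, or integer indices). Every burst must lie within `[0, total_s)`.
#' @param n_channels number of channels (default 100).
#' @param fs sampling rate in Hz (default 200, the working rate of the
#'   pipeline).
#' @param total_s total duration in seconds (default 600, a 10 min N2 nap
#'   segment).
#' @param noise_exponent spectral slope of the 1/f^exponent background
#'   (default 1).
#' @param seed integer seed making the recording bit-reproducible.
#' @return an object of class `"ground_truth"`.
#' @export
ground_truth <- function(bursts, n_channels = 100L, fs = 200, total_s = 600,
                         noise_exponent = 1, seed = 1L) {
  if (!is.data.frame(bursts)) stop("`bursts` must be a data.frame")
  need <- c("onset_s", "duration_s", "freq_hz", "amplitude_mult", "channels")
  miss <- setdiff(need, names(bursts))
  if (length(miss)) stop("bursts missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(bursts)) {
    if (any(bursts$onset_s < 0) ||
        any(bursts$onset_s + bursts$duration_s > total_s)) {
      stop("bursts must lie within [0, total_s)")
    }
    if (any(bursts$amplitude_mult <= 0)) stop("amplitude_mult must be positive")
    if (any(!nzchar(as.character(bursts$channels)))) {
      stop("every burst needs a non-empty channel set")
    }
  }
  structure(list(bursts = bursts, n_channels = as.integer(n_channels),
                 fs = fs, total_s = total_s, noise_exponent = noise_exponent,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Modality sensitivity profile
#'
#' Models the differential spatial sensitivity of a detection modality (e.g.
#' EEG vs. MEG source estimates) as a per-channel multiplicative gain on the
#' injected burst amplitude, plus the band in which that modality detects.
#'
#' @param name profile name.
#' @param sensitivity per-channel gains `>= 0` (length `n_channels`, or a
#'   scalar recycled).
#' @param detection_band numeric `c(lo, hi)` in Hz (default `c(12, 15)`).
#' @return an object of class `"modality_profile"`.
#' @export
modality_profile <- function(name = "uniform", sensitivity = 1,
                             detection_band = c(12, 15)) {
  if (any(sensitivity < 0)) stop("sensitivity gains must be >= 0")
  structure(list(name = name, sensitivity = as.numeric(sensitivity),
                 detection_band = as.numeric(detection_band)),
            class = "modality_profile")
}

# 1/f^expo noise, one channel per row, via FFT spectral shaping of white
# Gaussian noise. The DC component is zeroed.
pink_noise <- function(n_channels, n, fs, expo) {
  wh <- matrix(stats::rnorm(n_channels * n), nrow = n)
  W <- stats::mvfft(wh)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  shape <- c(0, f[-1L]^(-expo / 2))
  t(Re(stats::mvfft(W * shape, inverse = TRUE)) / n)
}

burst_channel_idx <- function(channels, channel_ids) {
  parts <- strsplit(as.character(channels), ";", fixed = TRUE)[[1L]]
  idx <- suppressWarnings(as.integer(parts))
  if (!anyNA(idx)) return(idx)
  m <- match(parts, channel_ids)
  if (anyNA(m)) stop("unknown burst channel(s): ",
                     paste(parts[is.na(m)], collapse = ", "))
  m
}

#' Generate a synthetic recording from a ground truth
#'
#' Background noise is seeded per-channel 1/f^exponent noise. Each burst
#' adds a Hanning-windowed sinusoid at `freq_hz` whose envelope peak equals
#' `amplitude_mult` times the channel's background sigma-band RMS (measured
#' in the profile's detection band) times the profile's channel gain, on the
#' listed channels. The hypnogram marks every full 30 s epoch as
#' artifact-free N2, and the injected intervals are returned per channel as
#' ground truth.
#'
#' @param gt a [ground_truth()].
#' @param profile a [modality_profile()] (default: uniform gain 1,
#'   band 12-15 Hz).
#' @return list with `recording`, `hypnogram`, `truth` (data.frame:
#'   `channel_id`, `start_s`, `end_s`, `freq_hz`, `amplitude_mult`,
#'   `burst_id`) and `sigma_rms` (per-channel background sigma-band RMS).
#' @examples
#' gt <- ground_truth(data.frame(onset_s = 5, duration_s = 1, freq_hz = 13.5,
#'                               amplitude_mult = 10, channels = "1;2;3"),
#'                    n_channels = 8, total_s = 30, seed = 7)
#' sim <- generate_recording(gt)
#' @export
generate_recording <- function(gt, profile = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (is.null(profile)) profile <- modality_profile()
  check_profile(gt, profile)
  render_modality(gt, simulate_background(gt, profile), profile)
}

check_profile <- function(gt, profile) {
  if (!length(profile$sensitivity) %in% c(1L, gt$n_channels)) {
    stop(sprintf("profile '%s' has %d gains for %d channels", profile$name,
                 length(profile$sensitivity), gt$n_channels))
  }
}

# Seeded background + per-channel sigma-band RMS, shared between modalities.
simulate_background <- function(gt, profile) {
  n <- as.integer(round(gt$total_s * gt$fs))
  noise <- with_seed(gt$seed,
                     pink_noise(gt$n_channels, n, gt$fs, gt$noise_exponent))
  rms <- apply(noise, 1L, function(x) {
    stats::sd(narrowband_channel(x, gt$fs, profile$detection_band[1L],
                                 profile$detection_band[2L]))
  })
  list(noise = noise, rms = rms)
}

render_modality <- function(gt, bg, profile) {
  n <- ncol(bg$noise)
  channel_ids <- sprintf("ch%03d", seq_len(gt$n_channels))
  gain <- rep_len(profile$sensitivity, gt$n_channels)
  data <- bg$noise
  truth <- list()
  for (b in seq_len(nrow(gt$bursts))) {
    bu <- gt$bursts[b, ]
    idx <- burst_channel_idx(bu$channels, channel_ids)
    nb <- as.integer(round(bu$duration_s * gt$fs))
    s0 <- as.integer(round(bu$onset_s * gt$fs)) + 1L
    k <- 0:(nb - 1L)
    env <- 0.5 - 0.5 * cos(2 * pi * k / (nb - 1L))
    carrier <- sin(2 * pi * bu$freq_hz * k / gt$fs)
    wave <- env * carrier
    for (ch in idx) {
      a <- bu$amplitude_mult * bg$rms[ch] * gain[ch]
      if (a > 0) {
        data[ch, s0:(s0 + nb - 1L)] <- data[ch, s0:(s0 + nb - 1L)] + a * wave
        truth[[length(truth) + 1L]] <- data.frame(
          channel_id = channel_ids[ch], start_s = bu$onset_s,
          end_s = bu$onset_s + bu$duration_s, freq_hz = bu$freq_hz,
          amplitude_mult = bu$amplitude_mult, burst_id = b)
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else {
    data.frame(channel_id = character(0), start_s = numeric(0),
               end_s = numeric(0), freq_hz = numeric(0),
               amplitude_mult = numeric(0), burst_id = integer(0))
  }
  n_ep <- as.integer(floor(gt$total_s / 30))
  list(recording = recording(data, fs = gt$fs, channel_ids = channel_ids,
                             modality = profile$name),
       hypnogram = hypnogram(rep("N2", n_ep)),
       truth = truth,
       sigma_rms = bg$rms)
}

#' Render the same ground truth under two modality profiles
#'
#' Both recordings share the same noise realization and the same bursts;
#' only the per-channel sensitivity gains differ. This enables controlled
#' tests of which events are common to, or unique to, each modality.
#'
#' @param gt a [ground_truth()].
#' @param profile_a,profile_b two [modality_profile()]s with gains for the
#'   same channel count.
#' @return list with `a`, `b` (each as returned by [generate_recording()]);
#'   the ground truth burst table is shared.
#' @export
generate_two_modality_pair <- function(gt, profile_a, profile_b) {
  check_profile(gt, profile_a)
  check_profile(gt, profile_b)
  bg <- simulate_background(gt, profile_a)
  list(a = render_modality(gt, bg, profile_a),
       b = render_modality(gt, bg, profile_b))
}

#' Default burst layout for the standard synthetic fixture
#'
#' Lays out `n_bursts` group-bursts with uniform spacing (at least
#' `min_sep_s` apart) at the given frequency, drawing each burst's channel
#' set at random under `seed`.
#'
#' @param n_bursts number of bursts (default 20).
#' @param total_s recording duration the bursts must fit in (default 600).
#' @param n_channels channel pool size (default 100).
#' @param extent_range range of channels per burst (default `c(3, 20)`).
#' @param amplitude_mult envelope peak relative to background sigma-band RMS
#'   (default 10).
#' @param duration_s burst duration in seconds (default 1, a typical
#'   spindle).
#' @param freq_hz carrier frequency (default 13.5, the fast-band center).
#' @param min_sep_s minimum onset-to-onset spacing (default 3).
#' @param seed integer seed for the channel draws.
#' @return data.frame suitable as the `bursts` argument of
#'   [ground_truth()].
#' @export
burst_layout <- function(n_bursts = 20L, total_s = 600, n_channels = 100L,
                         extent_range = c(3L, 20L), amplitude_mult = 10,
                         duration_s = 1, freq_hz = 13.5, min_sep_s = 3,
                         seed = 1L) {
  span <- (total_s - 2 * min_sep_s - duration_s) / max(1L, n_bursts - 1L)
  if (span < min_sep_s) stop("bursts do not fit: reduce n_bursts or min_sep_s")
  onsets <- min_sep_s + (seq_len(n_bursts) - 1L) * span
  with_seed(seed, {
    extents <- sample(extent_range[1L]:extent_range[2L], n_bursts,
                      replace = TRUE)
    chans <- vapply(extents, function(e) {
      paste(sample.int(n_channels, e), collapse = ";")
    }, "")
    data.frame(onset_s = onsets, duration_s = duration_s, freq_hz = freq_hz,
               amplitude_mult = amplitude_mult, channels = chans)
  })
}
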