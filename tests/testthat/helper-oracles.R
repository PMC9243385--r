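# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: direct time-domain convolution, explicit
# per-sample loops, exhaustive enumeration, power iteration.

# Smoothed Morlet amplitude by direct time-domain convolution.
oracle_wavelet_amplitude <- function(x, fs, band_lo, band_hi, smooth_s = 0.1) {
  fc <- (band_lo + band_hi) / 2
  sf <- (band_hi - band_lo) / (2 * sqrt(2 * log(2)))
  st <- 1 / (2 * pi * sf)
  half <- ceiling(5 * st * fs)
  tt <- (-half:half) / fs
  g <- exp(-tt^2 / (2 * st^2))
  k <- 2 * (g / sum(g)) * exp(2i * pi * fc * tt)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  raw <- vapply(seq_len(n), function(i) {
    Mod(sum(xp[i:(i + 2L * half)] * Conj(k)))
  }, 0)
  w <- 2L * floor(smooth_s * fs / 2) + 1L
  hw <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(raw[max(1L, i - hw):min(n, i + hw)])
  }, 0)
}

# Sample-wise energy thresholding with an explicit run state machine.
# Returns a matrix of (start_sample, end_sample) pairs (1-based, inclusive).
oracle_detect_runs <- function(x, fs, band_lo, band_hi, thresh_mult = 9,
                               min_dur_s = 0.4, smooth_s = 0.1) {
  a <- oracle_wavelet_amplitude(x, fs, band_lo, band_hi, smooth_s)
  e <- a^2
  thr <- thresh_mult * median(e)
  runs <- NULL
  start <- NA_integer_
  for (i in seq_along(e)) {
    if (e[i] > thr) {
      if (is.na(start)) start <- i
    } else if (!is.na(start)) {
      runs <- rbind(runs, c(start, i - 1L))
      start <- NA_integer_
    }
  }
  if (!is.na(start)) runs <- rbind(runs, c(start, length(e)))
  if (is.null(runs)) return(matrix(integer(0), ncol = 2))
  runs[(runs[, 2] - runs[, 1] + 1L) / fs >= min_dur_s - 1e-9, , drop = FALSE]
}

# Exhaustive maximum bipartite matching (cardinality first, total overlap as
# tie-break) over a sparse list of candidate pairs; feasible for <= 8 events
# per list.
oracle_max_matching <- function(pairs, n_test) {
  best <- list(size = 0L, overlap = 0)
  recurse <- function(i, used_test, size, overlap) {
    if (size > best$size ||
        (size == best$size && overlap > best$overlap)) {
      best <<- list(size = size, overlap = overlap)
    }
    if (i > nrow(pairs)) return()
    remaining <- nrow(pairs) - i + 1L
    if (size + remaining < best$size) return()
    # skip pair i
    recurse(i + 1L, used_test, size, overlap)
    # take pair i if free (pairs are grouped by ref, each ref used once)
    t <- pairs$test[i]
    if (!used_test[t]) {
      r <- pairs$ref[i]
      j <- i
      while (j <= nrow(pairs) && pairs$ref[j] == r) j <- j + 1L
      used_test[t] <- TRUE
      recurse(j, used_test, size + 1L, overlap + pairs$overlap[i])
    }
  }
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$ref, pairs$test), , drop = FALSE]
    recurse(1L, rep(FALSE, n_test), 0L, 0)
  }
  best
}

# Candidate overlap pairs between two event tables.
overlap_pairs <- function(ref, test, overlap_frac = 0.2, window_s = 1.0) {
  out <- NULL
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(nrow(test))) {
      ov <- min(ref$end_s[i], test$end_s[j]) -
        max(ref$start_s[i], test$start_s[j])
      if (ov >= overlap_frac * window_s - 1e-12) {
        out <- rbind(out, data.frame(ref = i, test = j, overlap = ov))
      }
    }
  }
  if (is.null(out)) data.frame(ref = integer(0), test = integer(0),
                               overlap = numeric(0)) else out
}

# Brute-force local maxima with the minimum-distance rule: enumerate every
# sample that is >= all samples within min_dist on both sides and strictly
# greater than its immediate non-equal neighbors, then apply highest-first
# suppression by explicit pairwise comparison.
oracle_peaks <- function(y, min_dist) {
  n <- length(y)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) {
        cand <- c(cand, i + (j - i) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  keep <- logical(length(cand))
  ord <- order(-y[cand], cand)
  for (a in ord) {
    ok <- TRUE
    for (b in seq_along(cand)) {
      if (keep[b] && abs(cand[a] - cand[b]) < min_dist) ok <- FALSE
    }
    keep[a] <- ok
  }
  sort(cand[keep])
}

# Dominant left singular vector by power iteration on X X^T.
oracle_first_left_sv <- function(x, n_iter = 1000L) {
  a <- x %*% t(x)
  v <- rep(1, nrow(x)) / sqrt(nrow(x))
  for (i in seq_len(n_iter)) {
    v2 <- a %*% v
    nv <- sqrt(sum(v2^2))
    if (nv == 0) break
    v2 <- v2 / nv
    if (max(abs(v2 - v)) < 1e-14 || max(abs(v2 + v)) < 1e-14) {
      v <- v2
      break
    }
    v <- v2
  }
  as.numeric(v)
}

# Exhaustive Otsu search: between-class variance from direct per-cut class
# statistics over the binned histogram.
oracle_otsu <- function(amps, n_bins = 256L) {
  edges <- seq(min(amps), max(amps), length.out = n_bins + 1L)
  bin <- pmin(findInterval(amps, edges, rightmost.closed = TRUE), n_bins)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  vals <- mids[bin]
  sb <- rep(-Inf, n_bins - 1L)
  for (k in seq_len(n_bins - 1L)) {
    lo <- vals[bin <= k]
    hi <- vals[bin > k]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(vals)
    sb[k] <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }
  # ties (flat criterion across an empty gap): take the plateau center
  best <- which(sb >= max(sb) * (1 - 1e-12))
  list(threshold = edges[as.integer(round(mean(best))) + 1L],
       between_var = max(sb))
}

# Single-channel 1/f noise through the package generator's seeded path.
pink1 <- function(n_samples, fs = 200, seed = 1L, expo = 1) {
  spindleloc:::with_seed(seed,
    as.numeric(spindleloc:::pink_noise(1L, n_samples, fs, expo)))
}

# Hanning-windowed sinusoidal burst added in place.
add_burst <- function(x, fs, onset_s, dur_s, freq_hz, amplitude) {
  nb <- round(dur_s * fs)
  k <- 0:(nb - 1L)
  s0 <- round(onset_s * fs) + 1L
  w <- amplitude * (0.5 - 0.5 * cos(2 * pi * k / (nb - 1L))) *
    sin(2 * pi * freq_hz * k / fs)
  x[s0:(s0 + nb - 1L)] <- x[s0:(s0 + nb - 1L)] + w
  x
}

# Band RMS of a signal via the package's zero-phase narrowband filter.
band_rms <- function(x, fs, lo = 12, hi = 15) {
  sd(spindleloc:::narrowband_channel(x, fs, lo, hi))
}

# Minimal event table from window centers.
event_table <- function(centers, window_s = 1.0, extent = 1L,
                        channels = "ch001") {
  if (!length(centers)) {
    return(data.frame(event_id = integer(0), center_s = numeric(0),
                      start_s = numeric(0), end_s = numeric(0),
                      extent = integer(0), channels = character(0)))
  }
  data.frame(event_id = seq_along(centers), center_s = centers,
             start_s = centers - window_s / 2, end_s = centers + window_s / 2,
             extent = rep_len(extent, length(centers)),
             channels = rep_len(channels, length(centers)))
}
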