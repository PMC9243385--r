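# Cross-modality comparison of spindle event lists: temporal-overlap
# matching with precision/recall/F1, spatial-extent correlation, FP
# topography, and sigma-power validation of unmatched events.

# Maximum-cardinality bipartite matching size over a set of candidate pairs.
max_matching_size <- function(pairs, n_ref, n_test) {
  if (!nrow(pairs)) return(0L)
  g <- igraph::make_empty_graph(n = n_ref + n_test, directed = FALSE)
  g <- igraph::add_edges(g, rbind(pairs$ref, n_ref + pairs$test))
  igraph::V(g)$type <- c(rep(FALSE, n_ref), rep(TRUE, n_test))
  igraph::max_bipartite_match(g)$matching_size
}

#' Match spindle events between two detection runs
#'
#' Two events (one from the reference list, one from the test list) are
#' compatible when their windows overlap by at least
#' `overlap_frac * window_s` seconds (default: at least 20% of the 1 s
#' window). Events are assigned one-to-one, preferring larger overlaps
#' (ties broken by earlier reference then test center), while always
#' realizing a maximum-cardinality matching so that no compatible pair is
#' left unmatched in favor of a smaller assignment. Unassigned test events
#' are false positives (FP), unassigned reference events false negatives
#' (FN), and
#' \deqn{f_P = TP/(TP+FP), \quad f_R = TP/(TP+FN), \quad
#'       F_1 = 2 f_P f_R / (f_P + f_R).}
#'
#' When both lists are empty all three scores are 1 (a recording without
#' spindles reproduced perfectly); when exactly one list is empty the
#' undefined ratio is set to 0.
#'
#' @param reference,test event data.frames (see [find_events()]) sorted by
#'   `center_s`, with windows of equal nominal length.
#' @param overlap_frac minimum overlap as a fraction of `window_s`, in
#'   (0, 1] (default 0.2).
#' @param window_s nominal window length in seconds (default 1).
#' @return object of class `"match_result"`: list with `TP` (data.frame of
#'   matched pairs: indices, centers, overlap, extents), `FP`, `FN` (row
#'   subsets of `test` / `reference`), counts `n_tp`, `n_fp`, `n_fn`, scores
#'   `fP`, `fR`, `F1`, and `overlap_frac`.
#' @export
match_events <- function(reference, test, overlap_frac = 0.2, window_s = 1.0) {
  if (!(overlap_frac > 0 && overlap_frac <= 1)) {
    stop("overlap_frac must be in (0, 1]")
  }
  n_ref <- nrow(reference)
  n_test <- nrow(test)
  min_ov <- overlap_frac * window_s
  pairs <- data.frame(ref = integer(0), test = integer(0),
                      overlap = numeric(0))
  if (n_ref && n_test) {
    ov <- outer(seq_len(n_ref), seq_len(n_test), function(i, j) {
      pmax(0, pmin(reference$end_s[i], test$end_s[j]) -
             pmax(reference$start_s[i], test$start_s[j]))
    })
    hit <- which(ov >= min_ov - 1e-12, arr.ind = TRUE)
    if (nrow(hit)) {
      pairs <- data.frame(ref = hit[, 1L], test = hit[, 2L],
                          overlap = ov[hit])
    }
  }
  target <- max_matching_size(pairs, n_ref, n_test)
  matched <- pairs[0, ]
  if (target > 0L) {
    ord <- order(-pairs$overlap, reference$center_s[pairs$ref],
                 test$center_s[pairs$test])
    pairs <- pairs[ord, , drop = FALSE]
    used_ref <- logical(n_ref)
    used_test <- logical(n_test)
    for (i in seq_len(nrow(pairs))) {
      r <- pairs$ref[i]
      t <- pairs$test[i]
      if (used_ref[r] || used_test[t]) next
      # keep this pair only if a maximum matching is still achievable
      rest <- pairs[-seq_len(i), , drop = FALSE]
      rest <- rest[!used_ref[rest$ref] & !used_test[rest$test] &
                     rest$ref != r & rest$test != t, , drop = FALSE]
      if (nrow(matched) + 1L + max_matching_size(rest, n_ref, n_test) >= target) {
        matched <- rbind(matched, pairs[i, , drop = FALSE])
        used_ref[r] <- TRUE
        used_test[t] <- TRUE
        if (nrow(matched) == target) break
      }
    }
  }
  n_tp <- nrow(matched)
  fp_idx <- setdiff(seq_len(n_test), matched$test)
  fn_idx <- setdiff(seq_len(n_ref), matched$ref)
  fP <- if (n_test > 0) n_tp / n_test else if (n_ref == 0) 1 else 0
  fR <- if (n_ref > 0) n_tp / n_ref else if (n_test == 0) 1 else 0
  F1 <- if (fP + fR > 0) 2 * fP * fR / (fP + fR) else 0
  tp <- data.frame(ref_idx = matched$ref, test_idx = matched$test,
                   overlap_s = matched$overlap,
                   ref_center_s = reference$center_s[matched$ref],
                   test_center_s = test$center_s[matched$test])
  if (!is.null(reference$extent)) tp$ref_extent <- reference$extent[matched$ref]
  if (!is.null(test$extent)) tp$test_extent <- test$extent[matched$test]
  tp <- tp[order(tp$ref_center_s), , drop = FALSE]
  structure(list(TP = tp,
                 FP = test[fp_idx, , drop = FALSE],
                 FN = reference[fn_idx, , drop = FALSE],
                 n_tp = n_tp, n_fp = length(fp_idx), n_fn = length(fn_idx),
                 fP = fP, fR = fR, F1 = F1, overlap_frac = overlap_frac,
                 window_s = window_s),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP=%d FP=%d FN=%d  fP=%.3f fR=%.3f F1=%.3f (overlap >= %g%%)\n",
              x$n_tp, x$n_fp, x$n_fn, x$fP, x$fR, x$F1, 100 * x$overlap_frac))
  invisible(x)
}

#' Correlation of spatial extents across matched events
#'
#' Ordinary least squares of the test-list extent on the reference-list
#' extent over the matched (TP) pairs, quantifying how well the spatial
#' extent of events transfers between modalities.
#'
#' @param matched either a `match_result` (its `TP` table must carry
#'   `ref_extent`/`test_extent`) or a data.frame with those two columns;
#'   at least 3 pairs.
#' @return list with `r_squared` (squared Pearson correlation), `slope`,
#'   `intercept` and `n`.
#' @export
extent_correlation <- function(matched) {
  tp <- if (inherits(matched, "match_result")) matched$TP else matched
  if (is.null(tp$ref_extent) || is.null(tp$test_extent)) {
    stop("matched pairs must carry ref_extent and test_extent")
  }
  if (nrow(tp) < 3L) stop("extent correlation needs at least 3 matched pairs")
  if (stats::var(tp$ref_extent) == 0 || stats::var(tp$test_extent) == 0) {
    stop("extent correlation undefined: zero variance in extents")
  }
  fit <- stats::lm(test_extent ~ ref_extent, data = tp)
  list(r_squared = stats::cor(tp$ref_extent, tp$test_extent)^2,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n = nrow(tp))
}

#' Topography of false-positive events
#'
#' For each channel, the percentage of FP events whose contributing-channel
#' set includes that channel, locating where events unique to one modality
#' tend to be detected.
#'
#' @param fp_events data.frame of FP events with a semicolon-joined
#'   `channels` column (as in [find_events()]).
#' @param channel_ids full channel set.
#' @return named numeric vector of percentages (all zero when there are no
#'   FPs).
#' @export
fp_topography <- function(fp_events, channel_ids) {
  out <- stats::setNames(numeric(length(channel_ids)), channel_ids)
  n_fp <- nrow(fp_events)
  if (!n_fp) return(out)
  sets <- strsplit(fp_events$channels, ";", fixed = TRUE)
  counts <- table(factor(unlist(lapply(sets, unique)), levels = channel_ids))
  out[] <- 100 * as.numeric(counts) / n_fp
  out
}

#' Sigma-band power validation of false-positive events
#'
#' Tests whether events detected in only one modality (FPs) nevertheless
#' carry elevated sigma-band power in the other modality's recording. The
#' recording is band-pass filtered to `[band_lo, band_hi]`, per-sample power
#' is taken as the squared magnitude of the analytic signal (Hilbert
#' transform), and each FP event's power is averaged over its window and
#' all channels. That average is z-normalized against `n_baseline` randomly
#' placed spindle-free windows of the same length (non-overlapping with any
#' event window and with each other, sampled without replacement under
#' `seed`): `z = (event mean - baseline mean) / baseline sd`. Events with
#' `z > z_crit` (default 1.69, a one-sided 5% criterion) are flagged as
#' showing elevated sigma power.
#'
#' @param rec a [recording()] covering every event window.
#' @param fp_events data.frame of FP events (windows `start_s`/`end_s`).
#' @param all_events data.frame of all events in this recording's modality;
#'   baseline windows avoid every one of these windows as well as the FP
#'   windows.
#' @param band_lo,band_hi sigma band in Hz (defaults 12 and 15).
#' @param n_baseline number of baseline windows (default 100).
#' @param z_crit elevation criterion (default 1.69).
#' @param seed integer seed for the baseline sampling (required for
#'   reproducibility).
#' @return list with per-event `z`, logical `elevated`, `frac_elevated`,
#'   `baseline_mean`, `baseline_sd`, `z_crit` and `n_baseline`.
#' @export
fp_sigma_power <- function(rec, fp_events, all_events, band_lo = 12,
                           band_hi = 15, n_baseline = 100, z_crit = 1.69,
                           seed) {
  stopifnot(inherits(rec, "recording"))
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required for reproducible baseline sampling")
  }
  fs <- rec$fs
  n <- n_samples(rec)
  win_s <- if (nrow(fp_events)) {
    stats::median(fp_events$end_s - fp_events$start_s)
  } else 1
  win_n <- as.integer(round(win_s * fs))
  power <- t(apply(rec$data, 1L, function(x) {
    Mod(analytic_signal(narrowband_channel(x, fs, band_lo, band_hi)))^2
  }))
  avoid <- rbind(all_events[, c("start_s", "end_s")],
                 fp_events[, c("start_s", "end_s")])
  free <- rep(TRUE, n)
  for (i in seq_len(nrow(avoid))) {
    rg <- interval_to_samples(avoid$start_s[i], avoid$end_s[i], fs, n)
    free[rg[1L]:rg[2L]] <- FALSE
  }
  # starts such that the whole window is spindle-free
  ok <- stats::filter(as.numeric(free), rep(1, win_n), sides = 1) == win_n
  cand <- which(c(ok[win_n:n], rep(FALSE, win_n - 1L)))
  bl_means <- with_seed(seed, {
    starts <- integer(0)
    pool <- cand
    while (length(starts) < n_baseline && length(pool)) {
      s <- pool[sample.int(length(pool), 1L)]
      starts <- c(starts, s)
      pool <- pool[abs(pool - s) >= win_n]
    }
    if (length(starts) < n_baseline) {
      stop(sprintf(
        "insufficient spindle-free time: placed %d of %d baseline windows",
        length(starts), n_baseline))
    }
    vapply(starts, function(s) mean(power[, s:(s + win_n - 1L)]), 0)
  })
  bl_mu <- mean(bl_means)
  bl_sd <- stats::sd(bl_means)
  z <- vapply(seq_len(nrow(fp_events)), function(i) {
    rg <- interval_to_samples(fp_events$start_s[i], fp_events$end_s[i], fs, n)
    (mean(power[, rg[1L]:rg[2L]]) - bl_mu) / bl_sd
  }, 0)
  elevated <- z > z_crit
  list(z = z, elevated = elevated,
       frac_elevated = if (length(z)) mean(elevated) else NA_real_,
       baseline_mean = bl_mu, baseline_sd = bl_sd, z_crit = z_crit,
       n_baseline = n_baseline)
}
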