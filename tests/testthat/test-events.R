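# Event builder: detection matrix, aggregate signal, local-maxima event
# windows with separation and extent rules, density.

iv <- function(channel, start, end) {
  data.frame(channel_id = channel, start_s = start, end_s = end)
}

test_that("detection matrix marks exactly the half-open interval samples", {
  ids <- c("a", "b", "c")
  dm0 <- build_detection_matrix(iv(character(0), numeric(0), numeric(0)),
                                ids, 200, 1000)
  expect_equal(sum(dm0$y), 0)
  dm1 <- build_detection_matrix(iv("b", 1.0, 1.5), ids, 200, 1000)
  expect_equal(sum(dm1$y["b", ]), 100)
  expect_equal(sum(dm1$y), 100)
  expect_equal(unname(dm1$y["b", 201]), 1L)  # sample at 1.000 s included
  expect_equal(unname(dm1$y["b", 301]), 0L)  # sample at 1.500 s excluded
  # overlapping intervals on one channel stay binary (union)
  dm2 <- build_detection_matrix(iv(c("a", "a"), c(1.0, 1.2), c(1.5, 1.8)),
                                ids, 200, 1000)
  expect_true(all(dm2$y %in% 0:1))
  expect_equal(sum(dm2$y["a", ]), 160)
  expect_error(build_detection_matrix(iv("z", 0, 1), ids, 200, 1000),
               "unknown channel")
})

test_that("aggregate signal sums channels and smooths with edge truncation", {
  ids <- sprintf("c%d", 1:3)
  cfg <- event_config()
  dm <- build_detection_matrix(iv(ids, rep(2.0, 3), rep(2.6, 3)), ids, 200,
                               1200)
  agg <- aggregate_detections(dm, cfg)
  expect_equal(max(agg$Y_raw), 3)
  expect_equal(max(agg$Y_smooth), 3)  # plateau wider than the 0.5 s window
  expect_true(all(agg$Y_smooth <= max(agg$Y_raw) + 1e-12))
  # all-zero matrix
  agg0 <- aggregate_detections(
    build_detection_matrix(iv(character(0), numeric(0), numeric(0)),
                           ids, 200, 1200), cfg)
  expect_equal(max(agg0$Y_smooth), 0)
  # single-sample detection: smoothed peak is 1 / window length
  dm1 <- build_detection_matrix(iv("c1", 3.0, 3.005), ids, 200, 1200)
  agg1 <- aggregate_detections(dm1, cfg)
  expect_equal(max(agg1$Y_smooth), 1 / 101)  # 0.5 s at 200 Hz -> 101 samples
})

test_that("events form at separated maxima with the extent floor", {
  fs <- 200
  cfg <- event_config()
  ids <- sprintf("ch%03d", 1:100)
  # one isolated 0.5 s detection on 5 of 100 channels
  dm <- build_detection_matrix(iv(ids[1:5], rep(5.0, 5), rep(5.5, 5)),
                               ids, fs, 20 * fs)
  ev <- find_events(aggregate_detections(dm, cfg), dm, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$extent, 5)
  expect_equal(ev$center_s, 5.25, tolerance = 0.05)
  expect_equal(ev$end_s - ev$start_s, 1.0)
  expect_setequal(strsplit(ev$channels, ";")[[1]], ids[1:5])
  # extent floor boundary (ceil(1% of 100) = 1, applied to the smoothed
  # aggregate): a lone channel detecting for at least the full smoothing
  # window reaches a smoothed peak of 1 and is kept ...
  dm1 <- build_detection_matrix(iv(ids[7], 5.0, 5.51), ids, fs, 20 * fs)
  ev1 <- find_events(aggregate_detections(dm1, cfg), dm1, cfg)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$extent, 1)
  # ... while a shorter isolated run smooths below the floor and is
  # discarded as spurious
  dm_short <- build_detection_matrix(iv(ids[7], 5.0, 5.45), ids, fs, 20 * fs)
  expect_equal(nrow(find_events(aggregate_detections(dm_short, cfg),
                                dm_short, cfg)), 0)
  # flat zero aggregate: no events
  dm0 <- build_detection_matrix(iv(character(0), numeric(0), numeric(0)),
                                ids, fs, 20 * fs)
  expect_equal(nrow(find_events(aggregate_detections(dm0, cfg), dm0, cfg)), 0)
})

test_that("close maxima merge under the separation rule, far ones stay", {
  fs <- 200
  cfg <- event_config()
  ids <- sprintf("ch%03d", 1:10)
  near <- build_detection_matrix(
    iv(c(ids[1:4], ids[1:2]), c(rep(5.0, 4), rep(5.45, 2)),
       c(rep(5.4, 4), rep(5.85, 2))), ids, fs, 20 * fs)
  agg_near <- aggregate_detections(near, cfg)
  ev_near <- find_events(agg_near, near, cfg)
  expect_equal(nrow(ev_near), 1)
  far <- build_detection_matrix(
    iv(c(ids[1:4], ids[1:2]), c(rep(5.0, 4), rep(6.2, 2)),
       c(rep(5.4, 4), rep(6.6, 2))), ids, fs, 20 * fs)
  agg_far <- aggregate_detections(far, cfg)
  ev_far <- find_events(agg_far, far, cfg)
  expect_equal(nrow(ev_far), 2)
  # both agree with brute-force maxima enumeration + suppression
  for (agg in list(agg_near, agg_far)) {
    expect_equal(spindleloc:::suppress_peaks(
      spindleloc:::local_maxima(agg$Y_smooth),
      agg$Y_smooth[spindleloc:::local_maxima(agg$Y_smooth)],
      cfg$min_peak_dist_s * fs),
      oracle_peaks(agg$Y_smooth, cfg$min_peak_dist_s * fs))
  }
})

test_that("event extent equals the window maximum of the raw aggregate", {
  fs <- 200
  cfg <- event_config()
  ids <- sprintf("ch%03d", 1:20)
  set.seed(9)
  starts <- sort(runif(15, 0, 55))
  intervals <- iv(sample(ids, 15, replace = TRUE), starts, starts + 0.45)
  dm <- build_detection_matrix(intervals, ids, fs, 60 * fs)
  agg <- aggregate_detections(dm, cfg)
  ev <- find_events(agg, dm, cfg)
  for (i in seq_len(nrow(ev))) {
    rg <- spindleloc:::interval_to_samples(ev$start_s[i], ev$end_s[i], fs,
                                           60 * fs)
    expect_equal(ev$extent[i], max(agg$Y_raw[rg[1]:rg[2]]))
  }
  # permuting channel order leaves the event set unchanged
  perm <- sample(ids)
  dm_p <- build_detection_matrix(intervals, perm, fs, 60 * fs)
  ev_p <- find_events(aggregate_detections(dm_p, cfg), dm_p, cfg)
  expect_equal(ev_p$center_s, ev$center_s)
  expect_equal(ev_p$extent, ev$extent)
  expect_equal(lapply(strsplit(ev_p$channels, ";"), sort),
               lapply(strsplit(ev$channels, ";"), sort))
  # centers at least min_peak_dist_s apart
  if (nrow(ev) > 1) expect_true(all(diff(ev$center_s) >= cfg$min_peak_dist_s))
})

test_that("windows crossing a concatenation seam are flagged", {
  fs <- 200
  cfg <- event_config()
  ids <- sprintf("ch%03d", 1:10)
  dm <- build_detection_matrix(iv(ids[1:3], rep(29.7, 3), rep(30.2, 3)),
                               ids, fs, 60 * fs)
  ev <- find_events(aggregate_detections(dm, cfg), dm, cfg, seams = 30)
  expect_equal(nrow(ev), 1)
  expect_true(ev$seam_crossing)
  ev2 <- find_events(aggregate_detections(dm, cfg), dm, cfg)
  expect_false(ev2$seam_crossing)
})

test_that("event density is events per minute", {
  expect_equal(event_density(data.frame(event_id = 1:20), 120), 10)
  expect_equal(event_density(data.frame(event_id = integer(0)), 120), 0)
  expect_equal(event_density(38, 38 * 60), 1)
  expect_error(event_density(5, 0), "positive")
})
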