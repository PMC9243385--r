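# Core data structures, container/EDF round trips, preprocessing and
# stage-restricted extraction.

test_that("recording constructor enforces its invariants", {
  expect_s3_class(recording(matrix(0, 2, 10), fs = 200), "recording")
  expect_error(recording(matrix(c(1, NA), 1, 2), fs = 200), "finite")
  expect_error(recording(matrix(0, 2, 10), fs = 0), "positive")
  expect_error(recording(matrix(0, 2, 10), fs = 200,
                         channel_ids = c("a", "a")), "distinct")
  expect_error(recording(matrix(0, 2, 10), fs = 200,
                         channel_ids = "a"), "one entry per channel")
})

test_that("container write/read round-trips data, metadata and shape", {
  set.seed(11)
  rec <- recording(matrix(rnorm(2 * 400), nrow = 2), fs = 200,
                   channel_ids = c("Fz", "Cz"), modality = "source-meg",
                   t0 = 1.5)
  path <- withr::local_tempfile(fileext = ".bin")
  write_recording(rec, path, "container")
  back <- read_recording(path, "container")
  expect_identical(back$data, rec$data)  # float64 storage is bit-exact
  expect_identical(back$channel_ids, c("Fz", "Cz"))
  expect_equal(back$fs, 200)
  expect_equal(back$t0, 1.5)
  expect_equal(back$modality, "source-meg")
  # float32 storage: read -> write -> read is stable at the stored precision
  write_recording(rec, path, "container", dtype = "float32")
  b1 <- read_recording(path)
  write_recording(b1, path, "container", dtype = "float32")
  expect_identical(read_recording(path)$data, b1$data)
  expect_lt(max(abs(b1$data - rec$data)), 1e-6 * max(abs(rec$data)))
})

test_that("EDF round trip stays within the 16-bit quantization step", {
  fs <- 200
  t <- (0:(4 * fs - 1)) / fs
  rec <- recording(rbind(50 * sin(2 * pi * 13 * t),
                         20 * cos(2 * pi * 5 * t),
                         rnorm(length(t))),
                   fs = fs, channel_ids = c("C3", "C4", "Oz"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$channel_ids, rec$channel_ids)
  expect_equal(back$fs, fs)
  expect_equal(dim(back$data), dim(rec$data))
  # per-channel quantization step of the symmetric 16-bit mapping
  for (i in 1:3) {
    step <- 2 * max(abs(rec$data[i, ])) * 1.0001 / 65535
    expect_lt(max(abs(back$data[i, ] - rec$data[i, ])), step)
  }
})

test_that("EDF files with mixed per-signal rates are rejected", {
  fs <- 200
  rec <- recording(matrix(rnorm(2 * fs), nrow = 2), fs = fs)
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  # corrupt the samples-per-record field of signal 2 (field-major layout:
  # nr fields start at 256 + ns*(16+80+8+8+8+8+8+80) for ns signals)
  con <- file(path, "r+b")
  seek(con, 256 + 2 * 216 + 8, rw = "write")
  writeBin(charToRaw(formatC("100", width = -8)), con)
  close(con)
  expect_error(read_recording(path), "unequal sampling rates")
})

test_that("hypnogram TSV round-trips with and without artifact column", {
  hyp <- hypnogram(c("WAKE", "N1", "N2", "N2", "N3", "N2"),
                   artifact = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hypnogram(hyp, path)
  back <- read_hypnogram(path)
  expect_equal(back$stages, hyp$stages)
  expect_equal(back$artifact, hyp$artifact)
  # two-column dialect, no header
  writeLines(c("1\tN2", "2\tWAKE"), path)
  back2 <- read_hypnogram(path)
  expect_equal(back2$stages, c("N2", "WAKE"))
  expect_equal(back2$artifact, c(FALSE, FALSE))
})

test_that("extract_stage selects exactly the requested non-artifact epochs", {
  fs <- 100
  rec <- recording(matrix(seq_len(2 * fs * 180), nrow = 2), fs = fs)
  hyp <- hypnogram(c("WAKE", "N1", "N2", "N2", "N3", "N2"))
  out <- extract_stage(rec, hyp, "N2")
  expect_equal(duration_s(out$recording), 90)
  expect_equal(nrow(out$intervals), 3)
  expect_equal(out$intervals$start_s, c(60, 90, 150))
  # concatenated samples come from the selected epochs, in order
  expect_equal(out$recording$data[1, 1], rec$data[1, 60 * fs + 1])
  # artifact flag removes an epoch
  hyp2 <- hypnogram(hyp$stages, artifact = c(F, F, F, T, F, F))
  out2 <- extract_stage(rec, hyp2, "N2")
  expect_equal(duration_s(out2$recording), 60)
  expect_equal(stage_seams(out2$intervals), 30)  # epochs 3 and 6 abut at 30 s
  # no matching epochs is an explicit error
  expect_error(extract_stage(rec, hyp, "REM"), "no non-artifact 'REM'")
})

test_that("preprocess passes the band, rejects stop-band and removes DC", {
  fs <- 600
  t <- (0:(20 * fs - 1)) / fs
  mk <- function(x) recording(matrix(x, nrow = 1), fs = fs)
  trim <- function(x) x[, (2 * 200):(ncol(x) - 2 * 200)]  # drop transients
  # 10 Hz sine survives with amplitude within 1%
  out <- preprocess(mk(sin(2 * pi * 10 * t)))
  expect_equal(out$fs, 200)
  expect_equal(max(abs(trim(out$data))), 1, tolerance = 0.01)
  # 50 Hz attenuated by >= 20 dB
  out50 <- preprocess(mk(sin(2 * pi * 50 * t)))
  expect_lt(max(abs(trim(out50$data))), 10^(-20 / 20))
  # DC rejected by the high-pass
  outdc <- preprocess(mk(rep(2, length(t))))
  expect_lt(sqrt(mean(trim(outdc$data)^2)), 0.01 * 2)
  # amplitude linearity
  x <- rnorm(length(t))
  expect_equal(preprocess(mk(3 * x))$data, 3 * preprocess(mk(x))$data,
               tolerance = 1e-10)
  # parameter validation
  expect_error(preprocess(mk(x), band_hi = 150), "band_hi < fs_out/2")
})
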