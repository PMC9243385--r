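# End-to-end orchestration: detect -> events -> optional match / fp-sigma /
# icc, with a JSON config, deterministic outputs and a run manifest.

default_config <- function() {
  list(stage = "N2",
       detector = list(band = "fast", smooth_s = 0.1, thresh_mult = 9,
                       min_dur_s = 0.4, dur_epoch_s = 2),
       events = list(smooth_s = 0.5, min_peak_dist_s = 0.5,
                     min_extent_frac = 0.01, window_s = 1.0),
       match = list(overlap_frac = 0.2),
       fp_sigma = list(band = c(12, 15), n_baseline = 100, z_crit = 1.69))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Fills in the standard parameter defaults (threshold multiplier 9, minimum
#' duration 0.4 s, coefficient smoothing 0.1 s, aggregate smoothing 0.5 s,
#' minimum extent 1%, window 1 s, overlap 20%, z criterion 1.69, 1000
#' bootstrap resamples) under any user overrides, and fails fast on missing
#' inputs or missing seeds for stochastic stages.
#'
#' @param config a list or the path of a JSON config file. Recognized
#'   top-level fields: `out_dir` (required), `seed`, `simulate` (parameters
#'   of [burst_layout()] / [ground_truth()]), `input` (list with
#'   `recording` and `hypnogram` paths), `stage`, `detector`, `events`,
#'   `match` (optionally with `reference_events` TSV path), `fp_sigma`
#'   (set `enabled = TRUE` to run; requires a seed), `icc` (with `sessions`
#'   TSV path and optionally `n_boot`).
#' @return validated config list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(default_config(), config)
  if (is.null(cfg$out_dir)) stop("config error: `out_dir` is required")
  if (is.null(cfg$simulate) && is.null(cfg$input)) {
    stop("config error: provide either `simulate` or `input`")
  }
  if (!is.null(cfg$input)) {
    for (f in c("recording", "hypnogram")) {
      if (is.null(cfg$input[[f]])) {
        stop("config error: input$", f, " is required")
      }
      if (!file.exists(cfg$input[[f]])) {
        stop("config error: missing file ", cfg$input[[f]])
      }
    }
  }
  if (!is.null(cfg$simulate) && is.null(cfg$seed)) {
    stop("config error: simulation requires a `seed`")
  }
  if (isTRUE(cfg$fp_sigma$enabled) &&
      is.null(cfg$fp_sigma$seed) && is.null(cfg$seed)) {
    stop("config error: fp_sigma requires a seed")
  }
  if (!is.null(cfg$match$reference_events) &&
      !file.exists(cfg$match$reference_events)) {
    stop("config error: missing file ", cfg$match$reference_events)
  }
  if (!is.null(cfg$icc) && !file.exists(cfg$icc$sessions %||% "")) {
    stop("config error: icc$sessions TSV is required")
  }
  cfg
}

#' Run the full spindle pipeline
#'
#' Executes, in order: input loading (or synthetic-data generation), stage
#' extraction, per-channel detection, event building, and the optional
#' match / sigma-power / ICC stages. All tabular artifacts (intervals,
#' events, match report) are written under `out_dir` together with a
#' `manifest.json` recording the package version, the fully-resolved config,
#' its hash, and the seeds used, so that identical configs and inputs yield
#' identical outputs. If any stage fails, outputs written so far are removed
#' and the error names the failing stage.
#'
#' @param config a config list or JSON path (see [load_config()]).
#' @return (invisibly) list with the stage results: `intervals`, `events`,
#'   `density`, and any of `match`, `fp_sigma`, `icc` that ran.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(writer, obj, name) {
    path <- file.path(cfg$out_dir, name)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  result <- list()
  stage_name <- "setup"
  tryCatch({
    stage_name <- "input"
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      lay_args <- sim_args[intersect(names(sim_args), names(formals(burst_layout)))]
      lay_args$seed <- cfg$seed
      bursts <- do.call(burst_layout, lay_args)
      gt <- ground_truth(bursts,
                         n_channels = sim_args$n_channels %||% 100L,
                         fs = sim_args$fs %||% 200,
                         total_s = sim_args$total_s %||% 600,
                         noise_exponent = sim_args$noise_exponent %||% 1,
                         seed = cfg$seed)
      sim <- generate_recording(gt)
      rec <- sim$recording
      hyp <- sim$hypnogram
      utils::write.table(sim$truth, file.path(cfg$out_dir, "truth.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      written <- c(written, file.path(cfg$out_dir, "truth.tsv"))
    } else {
      rec <- read_recording(cfg$input$recording)
      hyp <- read_hypnogram(cfg$input$hypnogram)
    }
    stage_name <- "extract_stage"
    ex <- extract_stage(rec, hyp, cfg$stage)
    seams <- stage_seams(ex$intervals, hyp$epoch_s)
    stage_name <- "detect"
    dcfg <- do.call(detector_config, cfg$detector)
    intervals <- detect_recording(ex$recording, dcfg)
    emit(write_intervals, intervals, "intervals.tsv")
    stage_name <- "events"
    ecfg <- do.call(event_config, cfg$events)
    events <- build_events(intervals, ex$recording$channel_ids,
                           ex$recording$fs, n_samples(ex$recording),
                           ecfg, seams)
    emit(write_events, events, "events.tsv")
    result$intervals <- intervals
    result$events <- events
    result$density <- event_density(events, duration_s(ex$recording))
    stage_name <- "match"
    if (!is.null(cfg$match$reference_events)) {
      ref <- read_events(cfg$match$reference_events)
      mr <- match_events(ref, events, cfg$match$overlap_frac,
                         ecfg$window_s)
      report <- list(n_tp = mr$n_tp, n_fp = mr$n_fp, n_fn = mr$n_fn,
                     fP = mr$fP, fR = mr$fR, F1 = mr$F1,
                     overlap_frac = mr$overlap_frac,
                     empty_lists_score_one = TRUE,
                     matched = mr$TP)
      path <- file.path(cfg$out_dir, "match.json")
      jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      written <- c(written, path)
      result$match <- mr
    }
    stage_name <- "fp_sigma"
    if (isTRUE(cfg$fp_sigma$enabled) && !is.null(result$match)) {
      fs_res <- fp_sigma_power(ex$recording, result$match$FP, events,
                               band_lo = cfg$fp_sigma$band[1L],
                               band_hi = cfg$fp_sigma$band[2L],
                               n_baseline = cfg$fp_sigma$n_baseline,
                               z_crit = cfg$fp_sigma$z_crit,
                               seed = cfg$fp_sigma$seed %||% cfg$seed)
      path <- file.path(cfg$out_dir, "fp_sigma.json")
      jsonlite::write_json(fs_res[c("z", "frac_elevated", "z_crit",
                                    "n_baseline")],
                           path, auto_unbox = TRUE, digits = NA)
      written <- c(written, path)
      result$fp_sigma <- fs_res
    }
    stage_name <- "icc"
    if (!is.null(cfg$icc)) {
      icc <- icc_bootstrap(read_sessions(cfg$icc$sessions),
                           n_boot = cfg$icc$n_boot %||% 1000L,
                           seed = cfg$icc$seed %||% cfg$seed)
      path <- file.path(cfg$out_dir, "icc.json")
      jsonlite::write_json(unclass(icc)[c("icc", "ci_lo", "ci_hi", "n_boot",
                                          "sigma2_between", "sigma2_within")],
                           path, auto_unbox = TRUE, digits = NA)
      written <- c(written, path)
      result$icc <- icc
    }
    stage_name <- "manifest"
    cfg_tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(cfg, cfg_tmp, auto_unbox = TRUE, digits = NA)
    manifest <- list(
      package = "spindleloc",
      version = as.character(utils::packageVersion("spindleloc")),
      config = cfg,
      config_hash = unname(tools::md5sum(cfg_tmp)),
      seed = cfg$seed,
      outputs = basename(written))
    unlink(cfg_tmp)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage_name,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
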