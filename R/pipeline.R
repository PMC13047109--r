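# End-to-end session processing: ingest -> calibrate -> epochs -> wear ->
# steps -> per-24-h metrics -> 48-h window summary.

#' Default run configuration
#'
#' Every tunable of the pipeline with its documented default; the config
#' round-trips losslessly through YAML/JSON.
#'
#' @return a named list of parameters.
#' @export
default_config <- function() {
  list(
    sample_rate_hz = 10,
    stationary = list(min_duration_s = 60, sd_threshold_g = 0.013,
                      window_s = 10),
    calibration = list(bias = 0, noise_floor = 0.013,
                       sigma_bar_sq = 0.013^2),
    nonwear = list(sd_threshold_g = 0.013, min_window_min = 90,
                   min_axes = 2, pad_min = 15, subblock_min = 30),
    motion = list(window_len_s = 5, moving_sd_g = 0.030, band_frac = 0.5),
    steps = list(amp_floor_g = 0.050, amp_rms_mult = 0.6),
    lwb = list(gap_s = 3, cap_s = 7200),
    aind = list(day_start_h = 7, day_end_h = 19, min_coverage = 0.5),
    validity = list(max_nonwear_h = 1.5, min_steps = 300),
    prompts = list(p_random_watch = 0.5, horizon_days = 84),
    engagement = list(block_days = 28, threshold = 0.5, n_required = 6),
    rounding = "half_up",
    seed = 1L
  )
}

#' Read / write a run configuration
#' @param path YAML file path.
#' @param config a config list (missing entries filled from defaults).
#' @return the config list (read) or the path, invisibly (write).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  cfg[names(user)] <- Map(function(d, u) {
    if (is.list(d) && is.list(u)) {
      d[names(u)] <- u
      d
    } else {
      u
    }
  }, cfg[names(user)], user)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# stable short hash of a config for run manifests
config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", hash31(as.character(js)))
}

#' Process one 48-h monitoring session end to end
#'
#' Runs ingestion, calibration (estimated from quiet-stationary intervals,
#' falling back to the configured defaults on short recordings), non-wear
#' detection, step detection and per-24-h metrics for the two
#' session-anchored intervals.
#'
#' @param raw a [raw_accel()] series in integer counts.
#' @param session_start session initiation time (seconds, series time
#'   base); defaults to the first sample time.
#' @param config a [default_config()]-shaped list.
#' @return list with `calibration`, `epochs`, `wear`, `steps`, `metrics`
#'   (two `daily_metrics`), and `window` (a [summarize_window()] result).
#' @export
process_session <- function(raw, session_start = NULL,
                            config = default_config()) {
  acc <- counts_to_g(raw)
  if (is.null(session_start)) session_start <- acc$t[1]
  stn <- find_stationary(acc,
                         min_duration_s = config$stationary$min_duration_s,
                         sd_threshold_g = config$stationary$sd_threshold_g,
                         window_s = config$stationary$window_s)
  cal <- tryCatch(
    estimate_calibration(acc, stn,
                         min_total_s = config$stationary$min_duration_s),
    remotewear_calibration_error = function(e) {
      calibration_params(bias = config$calibration$bias,
                         noise_floor = config$calibration$noise_floor,
                         sigma_bar_sq = config$calibration$sigma_bar_sq)
    })
  epochs <- epochize(acc, cal)
  wear <- detect_nonwear(epochs,
                         sd_threshold_g = config$nonwear$sd_threshold_g,
                         min_window_min = config$nonwear$min_window_min,
                         min_axes = config$nonwear$min_axes,
                         pad_min = config$nonwear$pad_min,
                         subblock_min = config$nonwear$subblock_min)
  motion <- classify_motion(acc,
                            window_len_s = config$motion$window_len_s,
                            moving_sd_g = config$motion$moving_sd_g,
                            band_frac = config$motion$band_frac)
  steps <- detect_steps(acc, motion = motion, wear = wear,
                        amp_floor_g = config$steps$amp_floor_g,
                        amp_rms_mult = config$steps$amp_rms_mult)
  ivs <- split_session(session_start, epochs, steps, wear)
  metrics <- lapply(ivs, daily_metrics, epochs = epochs, wear = wear,
                    cal = cal, gap_s = config$lwb$gap_s,
                    cap_s = config$lwb$cap_s,
                    day_window = c(config$aind$day_start_h,
                                   config$aind$day_end_h),
                    min_coverage = config$aind$min_coverage,
                    max_nonwear_h = config$validity$max_nonwear_h,
                    min_steps = config$validity$min_steps)
  list(calibration = cal, epochs = epochs, wear = wear, steps = steps,
       metrics = metrics,
       window = summarize_window(metrics[[1]], metrics[[2]]))
}

#' Process a session from a CSV file and write outputs
#'
#' Writes one row per 24-h interval (CSV + JSON) plus a run manifest
#' recording the config hash, seed and package version.
#'
#' @param input raw accelerometer CSV path.
#' @param out_dir output directory.
#' @param session_start session initiation time in seconds (default:
#'   start of recording).
#' @param config a config list.
#' @return the metrics data frame, invisibly.
#' @export
process_file <- function(input, out_dir, session_start = NULL,
                         config = default_config()) {
  raw <- read_raw(input, sample_rate = config$sample_rate_hz)
  res <- process_session(raw, session_start = session_start,
                         config = config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(res$metrics, daily_metrics_row))
  utils::write.csv(rows, file.path(out_dir, "daily_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(retained_aind = res$window$retained_aind,
         n_valid_intervals = res$window$n_valid_intervals),
    file.path(out_dir, "window_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = config$seed,
         package_version =
           as.character(utils::packageVersion("remotewear")),
         input = basename(input)),
    file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rows)
}
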