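# Raw wrist-accelerometer ingestion and calibration.
#
# The sensor delivers triaxial integer counts at 10 Hz over a +/-8 g range
# at 4,096 counts/g. Everything downstream works on calibrated gravity
# units (g) summarised into 1-second epochs.

COUNTS_PER_G <- 4096
COUNT_LIMIT <- 32768L
DEFAULT_RATE_HZ <- 10

#' Construct a raw triaxial sample series
#'
#' @param t numeric seconds since `anchor`; must be sortable, duplicates are
#'   collapsed (first kept).
#' @param x,y,z integer counts per axis (+/-8 g at 4,096 counts/g).
#' @param sample_rate nominal sampling rate in Hz.
#' @param device_id opaque device identifier.
#' @param anchor `POSIXct` local-clock anchor for `t = 0`.
#' @return a `raw_accel` data frame with columns `t, x, y, z`.
#' @export
raw_accel <- function(t, x, y, z, sample_rate = DEFAULT_RATE_HZ,
                      device_id = "unknown",
                      anchor = as.POSIXct("2000-01-01 00:00:00", tz = "UTC")) {
  if (!(length(t) == length(x) && length(t) == length(y) &&
          length(t) == length(z))) {
    stop_rw("remotewear_schema_error", "t, x, y, z must have equal length")
  }
  o <- order(t)
  t <- t[o]; x <- x[o]; y <- y[o]; z <- z[o]
  keep <- !duplicated(t)
  d <- data.frame(t = t[keep], x = x[keep], y = y[keep], z = z[keep])
  structure(d, class = c("raw_accel", "data.frame"),
            sample_rate = sample_rate, device_id = device_id,
            anchor = anchor)
}

#' Read a raw accelerometer CSV
#'
#' Expected schema (documented, bit-exact): header `time,x,y,z`; `time` is
#' either float seconds since the recording anchor or an ISO-8601 local
#' timestamp; `x`, `y`, `z` are integer counts. Gzipped files are accepted.
#' Rows are sorted by time, duplicate timestamps collapsed (first kept) and
#' gaps preserved -- no sample is ever interpolated.
#'
#' @param path CSV (optionally `.gz`) file path.
#' @param sample_rate nominal rate in Hz (default 10).
#' @param device_id device identifier to attach.
#' @param tz time zone for ISO-8601 timestamps.
#' @return a [raw_accel()] series.
#' @export
read_raw <- function(path, sample_rate = DEFAULT_RATE_HZ,
                     device_id = "unknown", tz = "UTC") {
  if (!file.exists(path)) {
    stop_rw("remotewear_io_error", "file not found: %s", path)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (nrow(d) == 0) {
    stop_rw("remotewear_empty_input", "empty accelerometer file: %s", path)
  }
  need <- c("time", "x", "y", "z")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_rw("remotewear_schema_error", "missing column(s): %s",
            paste(miss, collapse = ", "))
  }
  num_axis <- function(col) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) & nzchar(d[[col]]))
    if (length(bad)) {
      stop_rw("remotewear_parse_error",
              "non-numeric value in column '%s' at data line %d", col, bad[1])
    }
    v
  }
  tv <- suppressWarnings(as.numeric(d$time))
  if (anyNA(tv)) {
    ts <- as.POSIXct(d$time, tz = tz,
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(ts)) {
      stop_rw("remotewear_parse_error",
              "unparseable 'time' value at data line %d", which(is.na(ts))[1])
    }
    anchor <- ts[1]
    tv <- as.numeric(ts) - as.numeric(anchor)
  } else {
    anchor <- as.POSIXct("2000-01-01 00:00:00", tz = tz)
  }
  raw_accel(tv, num_axis("x"), num_axis("y"), num_axis("z"),
            sample_rate = sample_rate, device_id = device_id, anchor = anchor)
}

#' Convert integer counts to gravity units
#'
#' Exactly linear: `value_g = count / 4096` per axis; timestamps untouched.
#'
#' @param raw a [raw_accel()] series (integer counts).
#' @return an `accel_g` data frame with `t, x, y, z` in g and a `vm`
#'   vector-magnitude column.
#' @export
counts_to_g <- function(raw) {
  cnt <- c(raw$x, raw$y, raw$z)
  if (any(abs(cnt) > COUNT_LIMIT, na.rm = TRUE)) {
    stop_rw("remotewear_range_error",
            "count outside +/-%d (+/-8 g at 4,096 counts/g)", COUNT_LIMIT)
  }
  d <- data.frame(t = raw$t, x = raw$x / COUNTS_PER_G,
                  y = raw$y / COUNTS_PER_G, z = raw$z / COUNTS_PER_G)
  d$vm <- sqrt(d$x^2 + d$y^2 + d$z^2)
  structure(d, class = c("accel_g", "data.frame"),
            sample_rate = attr(raw, "sample_rate"),
            device_id = attr(raw, "device_id"),
            anchor = attr(raw, "anchor"))
}

#' Find quiet-stationary intervals
#'
#' A second is quiet when the vector-magnitude SD over the 10-s window
#' starting there stays below `sd_threshold_g`; maximal runs of quiet
#' seconds at least `min_duration_s` long (including the trailing window)
#' are returned as non-overlapping, sorted `[start, end)` intervals in the
#' series' own time base. These intervals feed [estimate_calibration()].
#'
#' @param acc an `accel_g` series.
#' @param min_duration_s minimum interval length, seconds (default 60).
#' @param sd_threshold_g VM-SD stillness threshold in g (default 0.013,
#'   i.e. 13 mg, the usual low-movement convention).
#' @param window_s sliding-window length in seconds (default 10).
#' @return data frame with columns `start`, `end` (seconds).
#' @export
find_stationary <- function(acc, min_duration_s = 60,
                            sd_threshold_g = 0.013, window_s = 10) {
  if (nrow(acc) == 0) {
    stop_rw("remotewear_empty_input", "empty acceleration series")
  }
  t0 <- acc$t[1]
  sec <- floor(acc$t - t0)
  nsec <- max(sec) + 1
  idx <- factor(sec, levels = 0:(nsec - 1))
  n <- as.numeric(table(idx))
  s1 <- rowsum_full(acc$vm, idx)
  s2 <- rowsum_full(acc$vm^2, idx)
  w <- window_s
  if (nsec < w) return(data.frame(start = numeric(0), end = numeric(0)))
  wn <- roll_sum(n, w)
  ws1 <- roll_sum(s1, w)
  ws2 <- roll_sum(s2, w)
  varw <- (ws2 - ws1^2 / pmax(wn, 1)) / pmax(wn - 1, 1)
  quiet <- wn >= 2 & sqrt(pmax(varw, 0)) < sd_threshold_g
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths + w - 1) >= min_duration_s
  data.frame(start = t0 + (starts[keep] - 1),
             end = t0 + (ends[keep] - 1) + w)
}

#' Calibration parameters
#'
#' `bias` is a scalar offset on the vector magnitude (g), `noise_floor` the
#' clamp threshold below which corrected deviations are zeroed (g), and
#' `sigma_bar_sq` the device's systematic per-axis noise variance (g^2)
#' used as the reference variance of the Activity Index.
#'
#' @param bias VM bias in g.
#' @param noise_floor clamp threshold in g (>= 0).
#' @param sigma_bar_sq systematic noise variance in g^2 (> 0).
#' @return a `calibration_params` list.
#' @export
calibration_params <- function(bias = 0, noise_floor = 0.013,
                               sigma_bar_sq = 0.013^2) {
  if (noise_floor < 0) {
    stop_rw("remotewear_config_error", "noise_floor must be >= 0")
  }
  if (sigma_bar_sq <= 0) {
    stop_rw("remotewear_config_error", "sigma_bar_sq must be > 0")
  }
  structure(list(bias = bias, noise_floor = noise_floor,
                 sigma_bar_sq = sigma_bar_sq),
            class = "calibration_params")
}

#' Default calibration used when no stationary data is available
#'
#' Zero bias, a 13 mg noise floor and (13 mg)^2 reference variance, so the
#' pipeline never aborts on short recordings.
#' @return a [calibration_params()] object.
#' @export
default_calibration <- function() calibration_params()

#' Estimate calibration from quiet-stationary intervals
#'
#' The bias is chosen so the median bias-corrected vector magnitude over
#' stationary samples equals 1 g; the noise floor is 3x the stationary VM
#' SD; the reference variance `sigma_bar_sq` is the mean per-axis variance
#' over stationary 1-s epochs (falling back to the default when the input
#' is perfectly noiseless).
#'
#' @param acc an `accel_g` series.
#' @param stationary intervals from [find_stationary()].
#' @param min_total_s minimum total stationary coverage (default 60 s).
#' @return a [calibration_params()] object.
#' @export
estimate_calibration <- function(acc, stationary, min_total_s = 60) {
  tot <- if (nrow(stationary)) sum(stationary$end - stationary$start) else 0
  if (tot < min_total_s) {
    stop_rw("remotewear_calibration_error",
            paste0("insufficient stationary data (%.0f s < %.0f s); ",
                   "fall back to default_calibration()"), tot, min_total_s)
  }
  inside <- rep(FALSE, nrow(acc))
  for (i in seq_len(nrow(stationary))) {
    inside <- inside |
      (acc$t >= stationary$start[i] & acc$t < stationary$end[i])
  }
  vm <- acc$vm[inside]
  bias <- stats::median(vm) - 1
  nf <- 3 * stats::sd(vm)
  sec <- floor(acc$t[inside] - acc$t[1])
  per_axis_var <- function(v) {
    as.numeric(tapply(v, sec, function(u) {
      if (length(u) >= 2) stats::var(u) else NA_real_
    }))
  }
  vx <- per_axis_var(acc$x[inside])
  vy <- per_axis_var(acc$y[inside])
  vz <- per_axis_var(acc$z[inside])
  sbsq <- mean(c(vx, vy, vz), na.rm = TRUE)
  if (!is.finite(sbsq) || sbsq <= 0) sbsq <- 0.013^2
  calibration_params(bias = bias, noise_floor = nf, sigma_bar_sq = sbsq)
}

#' Serialize calibration parameters to JSON
#' @param cal a [calibration_params()] object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
write_calibration <- function(cal, path = NULL) {
  js <- jsonlite::toJSON(unclass(cal), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read calibration parameters from JSON
#' @param path JSON file path.
#' @return a [calibration_params()] object.
#' @export
read_calibration <- function(path) {
  v <- jsonlite::fromJSON(path)
  calibration_params(bias = v$bias, noise_floor = v$noise_floor,
                     sigma_bar_sq = v$sigma_bar_sq)
}

#' Summarise calibrated acceleration into 1-second epochs
#'
#' Epoch boundaries are aligned to integer seconds from the recording's
#' first timestamp. Each elapsed second yields one record: per-axis mean
#' and SD, vector-magnitude mean/SD, and `vm_bc`, the bias-corrected
#' deviation of the VM from 1 g with values inside the noise floor (and any
#' residual negatives) clamped to zero. Seconds with no samples are emitted
#' with `n_samples = 0` and `NA` statistics, never dropped.
#'
#' @param acc an `accel_g` series.
#' @param cal a [calibration_params()] object.
#' @return an `epoch_series` data frame: `epoch_start`, `mean_x/y/z`,
#'   `sd_x/y/z`, `vm_mean`, `vm_sd`, `vm_bc`, `n_samples`.
#' @export
epochize <- function(acc, cal = default_calibration()) {
  if (nrow(acc) == 0) {
    stop_rw("remotewear_empty_input", "empty acceleration series")
  }
  t0 <- acc$t[1]
  sec <- floor(acc$t - t0)
  nsec <- max(sec) + 1
  idx <- factor(sec, levels = 0:(nsec - 1))
  n <- as.numeric(table(idx))
  stat <- function(v) {
    s1 <- rowsum_full(v, idx)
    s2 <- rowsum_full(v^2, idx)
    m <- ifelse(n > 0, s1 / n, NA_real_)
    va <- ifelse(n >= 2, (s2 - s1^2 / pmax(n, 1)) / pmax(n - 1, 1), 0)
    va[n == 0] <- NA_real_
    list(mean = m, sd = sqrt(pmax(va, 0)))
  }
  sx <- stat(acc$x); sy <- stat(acc$y); sz <- stat(acc$z)
  sv <- stat(acc$vm)
  dev <- sv$mean - 1 - cal$bias
  vm_bc <- ifelse(is.na(dev), NA_real_,
                  ifelse(abs(dev) < cal$noise_floor, 0, pmax(dev, 0)))
  d <- data.frame(
    epoch_start = t0 + 0:(nsec - 1),
    mean_x = sx$mean, mean_y = sy$mean, mean_z = sz$mean,
    sd_x = sx$sd, sd_y = sy$sd, sd_z = sz$sd,
    vm_mean = sv$mean, vm_sd = sv$sd, vm_bc = vm_bc,
    n_samples = as.integer(n)
  )
  structure(d, class = c("epoch_series", "data.frame"),
            sample_rate = attr(acc, "sample_rate"),
            device_id = attr(acc, "device_id"),
            anchor = attr(acc, "anchor"),
            calibration = cal)
}
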