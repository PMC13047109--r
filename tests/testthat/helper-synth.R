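# Shared builders and independent oracles for the test suite.

# epoch series built directly (bypassing the signal pipeline) for metric
# closed-form checks: constant per-axis SD, fully recorded
make_epoch_series <- function(n_sec, sd_axis, anchor_hour = 0,
                              vm_mean = 1) {
  anchor <- as.POSIXct(sprintf("2000-01-01 %02d:00:00", anchor_hour),
                       tz = "UTC")
  structure(data.frame(
    epoch_start = 0:(n_sec - 1),
    mean_x = 0, mean_y = 0, mean_z = vm_mean,
    sd_x = sd_axis, sd_y = sd_axis, sd_z = sd_axis,
    vm_mean = vm_mean, vm_sd = 0, vm_bc = 0,
    n_samples = 10L),
    class = c("epoch_series", "data.frame"),
    anchor = anchor, sample_rate = 10)
}

all_wear_mask <- function(n_sec) {
  list(wear = rep(TRUE, n_sec),
       segments = data.frame(start = numeric(0), end = numeric(0),
                             raw_start = numeric(0), raw_end = numeric(0),
                             duration_min = numeric(0), padded = logical(0)),
       record_min = n_sec / 60, t0 = 0, n_epochs = n_sec)
}

# Brute-force non-wear oracle: direct per-axis SD of raw samples per
# 30-min sub-block, then exhaustive enumeration of all >=90-min windows.
oracle_nonwear <- function(acc, sd_threshold_g = 0.013, min_window_min = 90,
                           min_axes = 2, pad_min = 15, subblock_min = 30) {
  t0 <- acc$t[1]
  nmin <- ceiling((floor(max(acc$t) - t0) + 1) / 60)
  n_starts <- nmin - subblock_min + 1
  if (n_starts < 1) return(data.frame(start = numeric(0), end = numeric(0)))
  quiet <- logical(n_starts)
  for (m in seq_len(n_starts) - 1) {
    j <- acc$t - t0 >= m * 60 & acc$t - t0 < (m + subblock_min) * 60
    nq <- sum(stats::sd(acc$x[j]) < sd_threshold_g,
              stats::sd(acc$y[j]) < sd_threshold_g,
              stats::sd(acc$z[j]) < sd_threshold_g)
    quiet[m + 1] <- nq >= min_axes
  }
  flagged <- rep(FALSE, nmin)
  for (a in 0:(nmin - min_window_min)) {
    for (b in (a + min_window_min):nmin) {
      ms <- a:(b - subblock_min)
      if (max(ms) + 1 > n_starts) next
      if (all(quiet[ms + 1])) flagged[(a + 1):b] <- TRUE
    }
  }
  r <- rle(flagged)
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  raw <- data.frame(start = s[r$values], end = e[r$values])
  if (!nrow(raw)) return(raw)
  m <- merge_intervals(pmax(raw$start - pad_min, 0),
                       pmin(raw$end + pad_min, nmin))
  data.frame(start = t0 + m$start * 60, end = t0 + m$end * 60)
}

# one-call gait fixture
gait_record <- function(cadence, duration_s = 60, seed = 7,
                        amplitude = 0.3, pad_s = 120) {
  segs <- data.frame(kind = "gait", duration_s = duration_s,
                     cadence = cadence, amplitude = amplitude)
  if (pad_s > 0) {
    pad <- data.frame(kind = "stationary_wear", duration_s = pad_s,
                      cadence = NA, amplitude = NA)
    segs <- rbind(pad, segs, pad)
  }
  generate_accel(activity_script(segs, seed = seed))
}
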