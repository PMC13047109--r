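# Non-wear detection from epoch-level axis variability.
#
# Rule family: a block is non-wear when per-axis SD stays below a small
# threshold on at least 2 of the 3 axes over a span of at least 90 min.
# Axis SD is evaluated over rolling 30-min sub-blocks stepping 1 min, which
# makes the rule local; detected blocks are padded by 15 min on each side
# to avoid edge effects, and padded minutes count as non-wear for the
# validity budget.

#' Detect non-wear periods
#'
#' @param epochs an `epoch_series` from [epochize()].
#' @param sd_threshold_g per-axis SD threshold in g (default 0.013).
#' @param min_window_min minimum non-wear span before padding (default 90).
#' @param min_axes number of quiet axes required (default 2).
#' @param pad_min padding added to each side of a detected block, minutes
#'   (default 15); padding never extends beyond the record.
#' @param subblock_min rolling sub-block length in minutes (default 30).
#' @return a `wear_mask`: list with `wear` (per-epoch logical), `segments`
#'   (padded non-wear segments with their pre-padding bounds) and the
#'   record span in minutes.
#' @export
detect_nonwear <- function(epochs, sd_threshold_g = 0.013,
                           min_window_min = 90, min_axes = 2,
                           pad_min = 15, subblock_min = 30) {
  if (sd_threshold_g <= 0 || min_window_min <= 0 || subblock_min <= 0 ||
        pad_min < 0) {
    stop_rw("remotewear_config_error", "non-positive non-wear parameter")
  }
  t0 <- epochs$epoch_start[1]
  nmin <- ceiling(nrow(epochs) / 60)
  empty_mask <- function() {
    structure(list(
      wear = rep(TRUE, nrow(epochs)),
      segments = data.frame(start = numeric(0), end = numeric(0),
                            raw_start = numeric(0), raw_end = numeric(0),
                            duration_min = numeric(0), padded = logical(0)),
      record_min = nrow(epochs) / 60, t0 = t0,
      n_epochs = nrow(epochs)), class = "wear_mask")
  }
  if (nmin < min_window_min) return(empty_mask())

  minute <- floor((epochs$epoch_start - t0) / 60)
  idx <- factor(minute, levels = 0:(nmin - 1))
  # Per-axis SD over a sub-block is the pooled raw-sample SD, rebuilt
  # exactly from per-epoch mean/SD/n: SS_i = (n_i - 1) sd_i^2 + n_i m_i^2.
  # Empty sub-blocks count as quiet (no evidence of wear), which also
  # makes the rule idempotent on mask-applied records.
  quiet_axis <- function(m, s) {
    ok <- !is.na(m)
    n_e <- ifelse(ok, epochs$n_samples, 0)
    s1_e <- ifelse(ok, n_e * m, 0)
    ss_e <- ifelse(ok, pmax(n_e - 1, 0) * s^2 + n_e * m^2, 0)
    n <- rowsum_full(n_e, idx)
    s1 <- rowsum_full(s1_e, idx)
    s2 <- rowsum_full(ss_e, idx)
    w <- subblock_min
    wn <- roll_sum(n, w)
    ws1 <- roll_sum(s1, w)
    ws2 <- roll_sum(s2, w)
    va <- (ws2 - ws1^2 / pmax(wn, 1)) / pmax(wn - 1, 1)
    sqrt(pmax(va, 0)) < sd_threshold_g | wn < 2
  }
  nq <- (quiet_axis(epochs$mean_x, epochs$sd_x) +
           quiet_axis(epochs$mean_y, epochs$sd_y) +
           quiet_axis(epochs$mean_z, epochs$sd_z))
  quiet <- nq >= min_axes  # one flag per sub-block start minute
  if (!length(quiet) || !any(quiet)) return(empty_mask())

  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths - 1 + subblock_min) >= min_window_min
  raw <- data.frame(start = (starts[keep] - 1),
                    end = (ends[keep] - 1) + subblock_min)  # minutes
  if (!nrow(raw)) return(empty_mask())
  raw <- merge_intervals(raw$start, raw$end)
  # padding guards against motion bleeding into the edges of a measured
  # quiet block; a side whose boundary minute holds no samples (data gap
  # or an already-masked record) needs no guard -- this also makes
  # detection idempotent on mask-applied records
  min_n <- rowsum_full(epochs$n_samples, idx)
  has_data <- function(m) m >= 0 & m < nmin & min_n[pmin(m, nmin - 1) + 1] > 0
  pad_l <- ifelse(has_data(raw$start), pad_min, 0)
  pad_r <- ifelse(has_data(raw$end - 1), pad_min, 0)
  pad <- merge_intervals(pmax(raw$start - pad_l, 0),
                         pmin(raw$end + pad_r, nmin))
  # map padded raw segments back for reporting (first covering raw bounds)
  seg <- data.frame(
    start = t0 + pad$start * 60, end = t0 + pad$end * 60,
    raw_start = NA_real_, raw_end = NA_real_,
    duration_min = pad$end - pad$start, padded = TRUE)
  for (i in seq_len(nrow(pad))) {
    in_i <- raw$start >= pad$start[i] - pad_min & raw$end <= pad$end[i] + pad_min
    seg$raw_start[i] <- t0 + min(raw$start[in_i]) * 60
    seg$raw_end[i] <- t0 + max(raw$end[in_i]) * 60
  }
  wear <- rep(TRUE, nrow(epochs))
  for (i in seq_len(nrow(seg))) {
    wear[epochs$epoch_start >= seg$start[i] &
           epochs$epoch_start < seg$end[i]] <- FALSE
  }
  structure(list(wear = wear, segments = seg,
                 record_min = nrow(epochs) / 60, t0 = t0,
                 n_epochs = nrow(epochs)),
            class = "wear_mask")
}

#' Total non-wear time of a mask, in minutes
#' @param mask a `wear_mask`.
#' @param interval optional `[start, end)` bounds in seconds to restrict to.
#' @param epochs the `epoch_series` the mask was computed on (needed when
#'   `interval` is given).
#' @return non-wear minutes.
#' @export
nonwear_minutes <- function(mask, interval = NULL, epochs = NULL) {
  if (is.null(interval)) return(sum(!mask$wear) / 60)
  stopifnot(!is.null(epochs))
  inb <- epochs$epoch_start >= interval[1] & epochs$epoch_start < interval[2]
  sum(!mask$wear[inb]) / 60
}

#' Export a wear mask as a 3-column status table
#' @param mask a `wear_mask`.
#' @param path optional CSV path.
#' @return data frame with `start`, `end`, `status`.
#' @export
wear_mask_table <- function(mask, path = NULL) {
  t0 <- mask$t0
  tend <- t0 + mask$n_epochs
  seg <- mask$segments
  bounds <- sort(unique(c(t0, seg$start, seg$end, tend)))
  out <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  out$status <- ifelse(
    vapply(out$start, function(s) any(s >= seg$start & s < seg$end), TRUE),
    "nonwear", "wear")
  out <- out[out$end > out$start, ]
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
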