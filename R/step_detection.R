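# Two-stage step detection for 10 Hz wrist accelerometry.
#
# Stage 1 labels 5-s windows "moving" / "not moving" from time-domain
# features of the triaxial signal (VM SD plus a dominant-frequency check in
# the gait band). Stage 2 band-passes the vector magnitude 0.6-2.5 Hz
# (zero-phase, so peak timestamps stay unbiased) and keeps regularly
# spaced, physiologically timed peak runs inside moving windows.

GAIT_BAND_HZ <- c(0.6, 2.5)
STEP_MIN_INTERVAL_S <- 0.33
STEP_MAX_INTERVAL_S <- 1.67
STEP_MAX_SPREAD_S <- 0.35
STEP_MIN_RUN <- 4

#' Classify short windows as moving or not moving
#'
#' Windows of `window_len_s` tile the record from its first timestamp; a
#' trailing partial window is labelled `not_moving`. A window is `moving`
#' when its VM SD reaches `moving_sd_g` AND its dominant frequency falls in
#' the gait band with at least `band_frac` of (DC-removed) spectral power
#' inside that band.
#'
#' @param acc an `accel_g` series at the nominal 10 Hz.
#' @param window_len_s window length in seconds (default 5).
#' @param moving_sd_g VM SD threshold in g (default 0.030).
#' @param band gait frequency band in Hz (default 0.6-2.5).
#' @param band_frac minimum in-band power fraction (default 0.5).
#' @return a `motion_windows` data frame with per-window features and a
#'   `label` column.
#' @export
classify_motion <- function(acc, window_len_s = 5, moving_sd_g = 0.030,
                            band = GAIT_BAND_HZ, band_frac = 0.5) {
  rate <- attr(acc, "sample_rate")
  n_w <- as.integer(window_len_s * rate)
  if (nrow(acc) < n_w) {
    stop_rw("remotewear_empty_input",
            "need at least one full %g-s window", window_len_s)
  }
  t0 <- acc$t[1]
  widx <- floor((acc$t - t0) / window_len_s)
  nwin <- max(widx) + 1
  out <- data.frame(window = 0:(nwin - 1))
  out$window_start <- t0 + out$window * window_len_s
  out$n <- as.integer(table(factor(widx, levels = out$window)))
  out$vm_sd <- NA_real_
  out$dom_freq <- NA_real_
  out$band_power_frac <- NA_real_
  out$label <- "not_moving"
  full <- which(out$n == n_w)
  sp <- split(acc$vm, widx)
  for (w in full) {
    v <- sp[[as.character(out$window[w])]]
    sdv <- stats::sd(v)
    pw <- Mod(stats::fft(v - mean(v)))^2
    half <- 2:(floor(n_w / 2) + 1)        # positive frequencies, DC removed
    fr <- (half - 1) * rate / n_w
    p <- pw[half]
    k <- which.max(p)
    inband <- fr >= band[1] & fr <= band[2]
    frac <- if (sum(p) > 0) sum(p[inband]) / sum(p) else 0
    out$vm_sd[w] <- sdv
    out$dom_freq[w] <- fr[k]
    out$band_power_frac[w] <- frac
    if (sdv >= moving_sd_g && fr[k] >= band[1] && fr[k] <= band[2] &&
          frac >= band_frac) {
      out$label[w] <- "moving"
    }
  }
  structure(out, class = c("motion_windows", "data.frame"),
            window_len_s = window_len_s, t0 = t0)
}

# Assemble peak times into maximal regular runs: successive intervals in
# [min_int, max_int] s and all intervals in a run within max_spread s of
# each other; runs shorter than min_run peaks are discarded.
regular_runs <- function(pt, min_int = STEP_MIN_INTERVAL_S,
                         max_int = STEP_MAX_INTERVAL_S,
                         max_spread = STEP_MAX_SPREAD_S,
                         min_run = STEP_MIN_RUN) {
  keep <- logical(length(pt))
  if (length(pt) == 0) return(keep)
  run_start <- 1
  run_min <- Inf
  run_max <- -Inf
  close_run <- function(a, b) if (b - a + 1 >= min_run) keep[a:b] <<- TRUE
  i <- 1
  while (i < length(pt)) {
    d <- pt[i + 1] - pt[i]
    ok <- d >= min_int && d <= max_int &&
      (max(run_max, d) - min(run_min, d)) <= max_spread
    if (ok) {
      run_min <- min(run_min, d)
      run_max <- max(run_max, d)
    } else {
      close_run(run_start, i)
      run_start <- i + 1
      run_min <- Inf
      run_max <- -Inf
    }
    i <- i + 1
  }
  close_run(run_start, length(pt))
  keep
}

#' Detect steps from 10 Hz vector-magnitude acceleration
#'
#' Within moving windows only, the VM is band-passed 0.6-2.5 Hz with a
#' zero-phase Butterworth filter; local maxima above an adaptive amplitude
#' threshold (`max(amp_floor_g, amp_rms_mult x` window band-passed RMS`)`)
#' become candidate peaks, and maximal runs of >= 4 peaks with successive
#' intervals in [0.33, 1.67] s differing pairwise by <= 0.35 s are emitted
#' as steps. Steps falling in non-wear epochs are removed, and no two
#' emitted steps are ever closer than 0.33 s.
#'
#' @param acc an `accel_g` series sampled at 10 Hz (the contract rate;
#'   other rates are rejected unless `resample = TRUE`).
#' @param motion optional precomputed [classify_motion()] result.
#' @param wear optional [detect_nonwear()] mask.
#' @param amp_floor_g absolute peak amplitude floor in g (default 0.050).
#' @param amp_rms_mult multiple of the window band-passed RMS (default 0.6).
#' @param resample linearly resample other rates to 10 Hz when `TRUE`.
#' @param ... threshold overrides passed to [classify_motion()].
#' @return a `step_events` data frame: `t`, `amplitude`, `window`.
#' @export
detect_steps <- function(acc, motion = NULL, wear = NULL,
                         amp_floor_g = 0.050, amp_rms_mult = 0.6,
                         resample = FALSE, ...) {
  rate <- attr(acc, "sample_rate")
  if (rate != DEFAULT_RATE_HZ) {
    if (!resample) {
      stop_rw("remotewear_rate_error",
              "sample rate %g Hz != contract rate %d Hz (set resample=TRUE)",
              rate, DEFAULT_RATE_HZ)
    }
    tt <- seq(acc$t[1], acc$t[nrow(acc)], by = 1 / DEFAULT_RATE_HZ)
    acc <- structure(
      data.frame(t = tt,
                 x = stats::approx(acc$t, acc$x, tt)$y,
                 y = stats::approx(acc$t, acc$y, tt)$y,
                 z = stats::approx(acc$t, acc$z, tt)$y,
                 vm = stats::approx(acc$t, acc$vm, tt)$y),
      class = c("accel_g", "data.frame"), sample_rate = DEFAULT_RATE_HZ,
      device_id = attr(acc, "device_id"), anchor = attr(acc, "anchor"))
    rate <- DEFAULT_RATE_HZ
  }
  if (is.null(motion)) motion <- classify_motion(acc, ...)
  win_len <- attr(motion, "window_len_s")
  empty <- structure(
    data.frame(t = numeric(0), amplitude = numeric(0), window = integer(0)),
    class = c("step_events", "data.frame"), anchor = attr(acc, "anchor"))
  moving <- motion$window[motion$label == "moving"]
  if (!length(moving)) return(empty)

  bf <- signal::butter(2, GAIT_BAND_HZ / (rate / 2), type = "pass")
  v <- signal::filtfilt(bf, acc$vm - mean(acc$vm))
  n <- length(v)
  is_peak <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] &
                 v[2:(n - 1)] > v[3:n], FALSE)
  t0 <- attr(motion, "t0")
  widx <- floor((acc$t - t0) / win_len)
  # adaptive per-window threshold over band-passed RMS
  rms <- tapply(v^2, widx, function(u) sqrt(mean(u)))
  win_ids <- as.numeric(names(rms))
  thr <- pmax(amp_floor_g, amp_rms_mult * as.numeric(rms))
  thr_s <- thr[match(widx, win_ids)]
  pk <- which(is_peak & widx %in% moving & v >= thr_s)
  if (!length(pk)) return(empty)
  pt <- acc$t[pk]
  keep <- regular_runs(pt)
  pk <- pk[keep]
  if (!length(pk)) return(empty)
  st <- data.frame(t = acc$t[pk], amplitude = v[pk],
                   window = as.integer(widx[pk]))
  if (!is.null(wear)) {
    seg <- wear$segments
    if (nrow(seg)) {
      drop <- vapply(st$t, function(x) any(x >= seg$start & x < seg$end),
                     TRUE)
      st <- st[!drop, , drop = FALSE]
    }
  }
  # physiologic floor across run boundaries as well
  if (nrow(st) > 1) {
    ok <- c(TRUE, diff(st$t) >= STEP_MIN_INTERVAL_S)
    while (!all(ok)) {
      st <- st[ok, , drop = FALSE]
      ok <- c(TRUE, diff(st$t) >= STEP_MIN_INTERVAL_S)
    }
  }
  rownames(st) <- NULL
  structure(st, class = c("step_events", "data.frame"),
            anchor = attr(acc, "anchor"))
}

#' Per-minute step counts on local-clock minute boundaries
#'
#' Minutes that intersect the record span get a count (possibly zero);
#' minutes fully outside wear (or outside the record) are `NA`, so "no
#' data" is distinguishable from "zero steps".
#'
#' @param steps a `step_events` data frame.
#' @param span `c(start, end)` record span in seconds.
#' @param wear optional [detect_nonwear()] mask; minutes fully inside
#'   non-wear segments are reported `NA`.
#' @param anchor optional `POSIXct` anchor; defaults to the one attached to
#'   `steps`.
#' @return data frame with `minute_start` (seconds), `n_steps`, `observed`.
#' @export
steps_per_minute <- function(steps, span, wear = NULL, anchor = NULL) {
  if (is.null(anchor)) anchor <- attr(steps, "anchor")
  off <- if (is.null(anchor)) 0 else as.numeric(anchor) %% 60
  m0 <- floor((span[1] + off) / 60)
  m1 <- ceiling((span[2] + off) / 60)
  mins <- m0:(m1 - 1)
  start <- mins * 60 - off
  n <- integer(length(mins))
  if (nrow(steps)) {
    b <- floor((steps$t + off) / 60)
    tb <- table(factor(b, levels = mins))
    n <- as.integer(tb)
  }
  observed <- rep(TRUE, length(mins))
  if (!is.null(wear) && nrow(wear$segments)) {
    seg <- wear$segments
    observed <- !vapply(seq_along(start), function(i) {
      any(start[i] >= seg$start & (start[i] + 60) <= seg$end)
    }, TRUE)
  }
  data.frame(minute_start = start,
             n_steps = ifelse(observed, n, NA_integer_),
             observed = observed)
}
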