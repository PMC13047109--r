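# Frailty-aligned per-24-h mobility metrics and 48-h session summaries.
#
# Each watch session is a 48-h window anchored at the moment the wearer
# pressed "Start monitoring"; it splits into up to two 24-h intervals.
# Metrics per interval: total steps (inactivity), 90th-percentile cadence
# (slowness), longest walking bout (endurance, capped at 2 h), and the
# variance-based Activity Index over daytime clock hours 07:00-19:00.
# Validity: <= 1.5 h non-wear and >= 300 steps (boundaries inclusive).

DAY_S <- 86400
LWB_CAP_S <- 7200

#' Split a 48-h session into two 24-h interval views
#'
#' Intervals are `[t0, t0+24h)` and `[t0+24h, t0+48h)` anchored at the
#' session initiation time, not calendar midnight. An interval containing
#' zero recorded epochs is marked `insufficient_coverage`.
#'
#' @param session_start session initiation time, seconds in the epoch
#'   series' time base.
#' @param epochs an `epoch_series`.
#' @param steps a `step_events` data frame.
#' @param wear a `wear_mask`.
#' @return list of two interval views: `start`, `end`, `epochs`, `steps`,
#'   `insufficient_coverage`.
#' @export
split_session <- function(session_start, epochs, steps, wear) {
  lapply(0:1, function(k) {
    s <- session_start + k * DAY_S
    e <- s + DAY_S
    inb <- epochs$epoch_start >= s & epochs$epoch_start < e &
      epochs$n_samples > 0
    list(interval_id = k + 1L, start = s, end = e,
         epochs = which(inb),
         steps = steps[steps$t >= s & steps$t < e, , drop = FALSE],
         insufficient_coverage = !any(inb))
  })
}

#' 90th-percentile cadence over stepping minutes
#'
#' The percentile (linear interpolation) is taken over minutes with at
#' least one detected step; an interval with no stepping minutes has
#' cadence 0 with `no_stepping_minutes = TRUE`.
#'
#' @param minute_counts data frame from [steps_per_minute()] (or any frame
#'   with an `n_steps` column).
#' @param prob percentile (default 0.9).
#' @return list with `cadence_p90` (steps/min) and `no_stepping_minutes`.
#' @export
compute_cadence <- function(minute_counts, prob = 0.9) {
  v <- minute_counts$n_steps
  v <- v[!is.na(v) & v >= 1]
  if (!length(v)) {
    return(list(cadence_p90 = 0, no_stepping_minutes = TRUE))
  }
  list(cadence_p90 = unname(stats::quantile(v, prob, type = 7)),
       no_stepping_minutes = FALSE)
}

#' Longest walking bout
#'
#' A bout is a maximal run of steps whose inter-step gaps are at most
#' `gap_s`; a bout is truncated at `cap_s` after its first step (steps in
#' `[first, first + cap_s)` count, duration reported as the capped span).
#' The LWB is the bout with most steps; ties go to the earliest.
#'
#' @param step_times numeric step timestamps (seconds), sorted.
#' @param gap_s maximum inter-step gap preserving a bout (default 3 s).
#' @param cap_s bout cap in seconds (default 7200 = 2 h).
#' @return list with `lwb_steps`, `lwb_duration_s`, `lwb_start`.
#' @export
compute_lwb <- function(step_times, gap_s = 3, cap_s = LWB_CAP_S) {
  if (length(step_times) == 0) {
    return(list(lwb_steps = 0L, lwb_duration_s = 0, lwb_start = NA_real_))
  }
  st <- sort(step_times)
  brk <- c(0, cumsum(diff(st) > gap_s))
  best <- list(lwb_steps = 0L, lwb_duration_s = 0, lwb_start = NA_real_)
  for (b in split(st, brk)) {
    first <- b[1]
    n <- sum(b < first + cap_s)
    dur <- min(b[length(b)] - first, cap_s)
    if (n > best$lwb_steps) {
      best <- list(lwb_steps = as.integer(n), lwb_duration_s = dur,
                   lwb_start = first)
    }
  }
  best
}

#' Activity Index over daytime hours of an interval
#'
#' Per 1-s epoch, `AI_t = sqrt(max(0, mean_axes((sigma2_axis -
#' sigma_bar_sq) / sigma_bar_sq)))`: the average per-axis variance in
#' excess of the device's systematic noise variance, on a square-root
#' scale. Hourly summaries sum `AI_t` over worn epochs in each local-clock
#' hour; the daily value sums the hours intersecting the daytime window
#' (07:00-19:00 by default) inside the interval. Non-wear epochs
#' contribute 0. The value is reported missing when less than
#' `min_coverage` of the interval's daytime epochs are worn and present.
#'
#' @param epochs an `epoch_series`.
#' @param cal a [calibration_params()] object (`sigma_bar_sq > 0`).
#' @param wear a `wear_mask` computed on `epochs`.
#' @param interval `c(start, end)` bounds in seconds.
#' @param day_window daytime local-clock hours, default `c(7, 19)`.
#' @param min_coverage minimum fraction of daytime epochs that must be
#'   worn and recorded (default 0.5).
#' @return list with `aind_daily`, `coverage`, `missing`.
#' @export
compute_aind <- function(epochs, cal, wear, interval,
                         day_window = c(7, 19), min_coverage = 0.5) {
  if (cal$sigma_bar_sq <= 0) {
    stop_rw("remotewear_config_error", "sigma_bar_sq must be > 0")
  }
  anchor <- attr(epochs, "anchor")
  off <- if (is.null(anchor)) 0 else as.numeric(anchor)
  abs_t <- off + epochs$epoch_start
  hr <- (abs_t %% DAY_S) / 3600
  inb <- epochs$epoch_start >= interval[1] & epochs$epoch_start < interval[2]
  day <- hr >= day_window[1] & hr < day_window[2]
  sel <- inb & day
  present <- sel & epochs$n_samples > 0 & wear$wear
  v <- (epochs$sd_x^2 + epochs$sd_y^2 + epochs$sd_z^2) / 3
  ai <- sqrt(pmax(0, (v - cal$sigma_bar_sq) / cal$sigma_bar_sq))
  total_day_s <- (day_window[2] - day_window[1]) * 3600 *
    (interval[2] - interval[1]) / DAY_S
  coverage <- if (total_day_s > 0) sum(present) / total_day_s else 0
  list(aind_daily = sum(ai[present], na.rm = TRUE),
       coverage = coverage,
       missing = coverage < min_coverage)
}

#' Apply per-interval validity rules
#'
#' Valid iff non-wear <= `max_nonwear_h`, total steps >= `min_steps` (both
#' boundaries inclusive) and the interval had any recorded coverage.
#'
#' @param metrics a `daily_metrics` row list (see [daily_metrics()]).
#' @param max_nonwear_h non-wear budget in hours (default 1.5).
#' @param min_steps minimum step count (default 300).
#' @return `metrics` with `valid` and `invalid_reasons` filled in.
#' @export
filter_valid <- function(metrics, max_nonwear_h = 1.5, min_steps = 300) {
  reasons <- character(0)
  if (isTRUE(metrics$insufficient_coverage)) {
    reasons <- c(reasons, "insufficient_coverage")
  }
  if (metrics$nonwear_h > max_nonwear_h) {
    reasons <- c(reasons, "excess_nonwear")
  }
  if (metrics$total_steps < min_steps) {
    reasons <- c(reasons, "too_few_steps")
  }
  metrics$valid <- length(reasons) == 0
  metrics$invalid_reasons <- reasons
  metrics
}

#' Compute all per-24-h metrics for one interval view
#'
#' @param iv one interval view from [split_session()].
#' @param epochs,wear,cal the session's epoch series, wear mask and
#'   calibration.
#' @param gap_s,cap_s LWB parameters (see [compute_lwb()]).
#' @param day_window,min_coverage Activity Index parameters.
#' @param max_nonwear_h,min_steps validity parameters.
#' @return a `daily_metrics` list.
#' @export
daily_metrics <- function(iv, epochs, wear, cal, gap_s = 3,
                          cap_s = LWB_CAP_S, day_window = c(7, 19),
                          min_coverage = 0.5, max_nonwear_h = 1.5,
                          min_steps = 300) {
  spm <- steps_per_minute(iv$steps, c(iv$start, iv$end), wear = wear,
                          anchor = attr(epochs, "anchor"))
  cad <- compute_cadence(spm)
  lwb <- compute_lwb(iv$steps$t, gap_s = gap_s, cap_s = cap_s)
  ai <- compute_aind(epochs, cal, wear, c(iv$start, iv$end),
                     day_window = day_window, min_coverage = min_coverage)
  m <- list(
    interval_id = iv$interval_id,
    start = iv$start, end = iv$end,
    total_steps = nrow(iv$steps),
    cadence_p90 = cad$cadence_p90,
    lwb_steps = lwb$lwb_steps,
    lwb_duration_s = lwb$lwb_duration_s,
    aind_daily = if (ai$missing) NA_real_ else ai$aind_daily,
    aind_coverage = ai$coverage,
    nonwear_h = nonwear_minutes(wear, c(iv$start, iv$end), epochs) / 60,
    insufficient_coverage = iv$insufficient_coverage
  )
  filter_valid(m, max_nonwear_h = max_nonwear_h, min_steps = min_steps)
}

#' Summarise a 48-h session from its two 24-h interval metrics
#'
#' The retained Activity Index is the larger of the available 24-h
#' summaries; `n_valid_intervals` counts only intervals passing the step
#' validity rules.
#'
#' @param m1,m2 `daily_metrics` lists (either may be `NULL`).
#' @param session_id identifier to attach.
#' @return a `window_summary` list.
#' @export
summarize_window <- function(m1, m2 = NULL, session_id = NA) {
  ms <- Filter(Negate(is.null), list(m1, m2))
  ainds <- vapply(ms, function(m) {
    if (is.null(m$aind_daily)) NA_real_ else m$aind_daily
  }, 0)
  retained <- if (all(is.na(ainds))) NA_real_ else max(ainds, na.rm = TRUE)
  list(session_id = session_id,
       retained_aind = retained,
       n_valid_intervals = sum(vapply(ms, function(m) isTRUE(m$valid), TRUE)),
       intervals = ms)
}

#' Flatten daily metrics to a one-row data frame
#' @param m a `daily_metrics` list.
#' @return one-row data frame (reasons collapsed with `;`).
#' @export
daily_metrics_row <- function(m) {
  data.frame(
    interval_id = m$interval_id, start = m$start, end = m$end,
    total_steps = m$total_steps, cadence_p90 = m$cadence_p90,
    lwb_steps = m$lwb_steps, lwb_duration_s = m$lwb_duration_s,
    aind_daily = m$aind_daily, aind_coverage = m$aind_coverage,
    nonwear_h = m$nonwear_h, valid = m$valid,
    invalid_reasons = paste(m$invalid_reasons, collapse = ";"))
}
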