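# Synthetic wrist-accelerometry and cohort generators with ground truth.
#
# Scripted days are built from contiguous segments of three kinds:
#   gait            band-limited periodic VM oscillation at the scripted
#                   cadence (two-harmonic waveform, closed-form step count)
#   stationary_wear gravity + sensor noise + brief scripted wrist fidgets,
#                   so quiet worn skin time stays distinguishable from
#                   non-wear under a variance-only rule
#   nonwear         gravity + near-zero noise (device off wrist)
# Everything is deterministic per seed.

#' Build an activity script
#'
#' @param segments data frame with columns `kind` (gait /
#'   stationary_wear / nonwear), `duration_s`, and optionally `cadence`
#'   (steps/min, gait), `amplitude` (g, gait), `noise_sd` (g).
#' @param seed integer seed.
#' @param start_s recording start time in seconds (default 0).
#' @param anchor `POSIXct` local-clock anchor for `t = 0`.
#' @return an `activity_script` list.
#' @export
activity_script <- function(segments, seed = 1L, start_s = 0,
                            anchor = as.POSIXct("2000-01-01 00:00:00",
                                                tz = "UTC")) {
  need <- c("kind", "duration_s")
  if (!all(need %in% names(segments))) {
    stop_rw("remotewear_config_error",
            "segments need columns: %s", paste(need, collapse = ", "))
  }
  if (any(segments$duration_s <= 0)) {
    stop_rw("remotewear_config_error", "segment durations must be > 0")
  }
  if (!all(segments$kind %in% c("gait", "stationary_wear", "nonwear"))) {
    stop_rw("remotewear_config_error", "unknown segment kind")
  }
  if (is.null(segments$cadence)) segments$cadence <- NA_real_
  if (is.null(segments$amplitude)) segments$amplitude <- NA_real_
  if (is.null(segments$noise_sd)) segments$noise_sd <- NA_real_
  g <- segments$kind == "gait"
  segments$cadence[g][is.na(segments$cadence[g])] <- 100
  segments$amplitude[g][is.na(segments$amplitude[g])] <- 0.3
  segments$noise_sd[is.na(segments$noise_sd)] <-
    ifelse(segments$kind[is.na(segments$noise_sd)] == "nonwear", 0.002, 0.008)
  if (any(g & (segments$cadence < 30 | segments$cadence > 200))) {
    stop_rw("remotewear_config_error", "cadence must lie in [30, 200]")
  }
  if (any(g & segments$amplitude <= 0)) {
    stop_rw("remotewear_config_error", "gait amplitude must be > 0")
  }
  structure(list(segments = segments, seed = as.integer(seed),
                 start_s = start_s, anchor = anchor),
            class = "activity_script")
}

#' Generate a raw accelerometer series from a script
#'
#' Gait is rendered on the z axis as `1 + A (sin(2 pi f t) +
#' 0.3 sin(4 pi f t))` with `f = cadence / 60` Hz plus Gaussian noise;
#' every fundamental period carries exactly one step, so the true step
#' count per gait segment is `floor(duration x f)`. Stationary wear adds
#' a brief 0.3 g wrist fidget every `fidget_every_s` so that worn quiet
#' time exceeds per-axis non-wear SD thresholds over long blocks while
#' leaving >= 60 s quiet stretches for calibration; non-wear is gravity
#' plus 2 mg noise. Output is identical for identical seeds.
#'
#' @param script an [activity_script()].
#' @param rate_hz sampling rate (default 10).
#' @param fidget_every_s fidget spacing in stationary wear (default 90 s).
#' @return list with `raw` (a [raw_accel()] in integer counts) and
#'   `truth` (per-segment step counts, non-wear minutes, bout bounds).
#' @export
generate_accel <- function(script, rate_hz = DEFAULT_RATE_HZ,
                           fidget_every_s = 90) {
  segs <- script$segments
  stream <- new_rng_stream(script$seed)
  dt <- 1 / rate_hz
  xs <- list(); ys <- list(); zs <- list()
  truth_steps <- numeric(nrow(segs))
  bout_rows <- list()
  t_cursor <- script$start_s
  for (i in seq_len(nrow(segs))) {
    dur <- segs$duration_s[i]
    n <- round(dur * rate_hz)
    tt <- t_cursor + (0:(n - 1)) * dt
    noise <- segs$noise_sd[i]
    ex <- with_stream(stream, stats::rnorm(n, 0, noise))
    ey <- with_stream(stream, stats::rnorm(n, 0, noise))
    ez <- with_stream(stream, stats::rnorm(n, 0, noise))
    if (segs$kind[i] == "gait") {
      f <- segs$cadence[i] / 60
      ph <- 2 * pi * f * (tt - t_cursor)
      # arm swing moves all three axes; the z (gravity) axis carries the
      # dominant step oscillation
      z <- 1 + segs$amplitude[i] * (sin(ph) + 0.3 * sin(2 * ph)) + ez
      x <- 0.4 * segs$amplitude[i] * sin(ph + pi / 3) + ex
      y <- 0.35 * segs$amplitude[i] * sin(ph + 2 * pi / 3) + ey
      truth_steps[i] <- floor(dur * f)
      bout_rows <- c(bout_rows, list(data.frame(
        start = t_cursor, end = t_cursor + dur,
        cadence = segs$cadence[i], steps = truth_steps[i])))
    } else {
      z <- 1 + ez
      x <- ex
      y <- ey
      if (segs$kind[i] == "stationary_wear" && dur > fidget_every_s) {
        # brief wrist rotations perturb two axes, so worn quiet time is
        # not mistaken for non-wear under the >=2-quiet-axes rule
        ft <- seq(fidget_every_s, dur - 1, by = fidget_every_s)
        for (f0 in ft) {
          j <- which(tt - t_cursor >= f0 & tt - t_cursor < f0 + 1)
          bump <- 0.3 * sin(pi * (tt[j] - t_cursor - f0))
          x[j] <- x[j] + bump
          z[j] <- z[j] - bump
        }
      }
    }
    xs[[i]] <- x; ys[[i]] <- y; zs[[i]] <- z
    t_cursor <- t_cursor + dur
  }
  nmin_true <- sum(segs$duration_s[segs$kind == "nonwear"]) / 60
  n_all <- sum(vapply(xs, length, 0L))
  t_all <- script$start_s + (0:(n_all - 1)) * dt
  to_counts <- function(v) {
    as.integer(pmax(pmin(round(v * COUNTS_PER_G), COUNT_LIMIT), -COUNT_LIMIT))
  }
  raw <- raw_accel(t_all, to_counts(unlist(xs)), to_counts(unlist(ys)),
                   to_counts(unlist(zs)), sample_rate = rate_hz,
                   device_id = "synthetic", anchor = script$anchor)
  list(raw = raw,
       truth = list(
         segment_steps = truth_steps,
         total_steps = sum(truth_steps),
         nonwear_min = nmin_true,
         nonwear_segments = {
           cum <- cumsum(c(script$start_s, segs$duration_s))
           k <- segs$kind == "nonwear"
           data.frame(start = cum[-length(cum)][k], end = cum[-1][k])
         },
         bouts = if (length(bout_rows)) do.call(rbind, bout_rows)
                 else data.frame(start = numeric(0), end = numeric(0),
                                 cadence = numeric(0), steps = numeric(0))))
}

#' Generate a simulation cohort config
#'
#' Per-participant behavior probabilities default to the pilot-observed
#' rates (see [behavior_model()]); each participant receives distinct
#' named RNG substreams derived from the seed at simulation time.
#'
#' @param n number of participants (>= 1).
#' @param seed integer seed recorded in the config.
#' @param behavior common overrides passed to [behavior_model()] (e.g.
#'   `list(p_down = 0.4)`).
#' @return a cohort config list consumable by [run_simulation()].
#' @export
generate_cohort <- function(n = 10, seed = 1L, behavior = list()) {
  if (n < 1) stop_rw("remotewear_config_error", "n must be >= 1")
  do.call(behavior_model, behavior)  # validates probabilities
  list(seed = as.integer(seed),
       participants = lapply(seq_len(n), function(i) {
         list(id = sprintf("P%02d", i), behavior = behavior)
       }))
}

#' Write an activity script / cohort config as YAML
#' @param x an [activity_script()] or cohort config.
#' @param path YAML file path.
#' @return the path, invisibly.
#' @export
write_config_yaml <- function(x, path) {
  obj <- if (inherits(x, "activity_script")) {
    list(seed = x$seed, start_s = x$start_s,
         anchor = format(x$anchor, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
         segments = lapply(seq_len(nrow(x$segments)), function(i) {
           as.list(x$segments[i, ])
         }))
  } else {
    x
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read an activity script from YAML
#' @param path YAML file path.
#' @return an [activity_script()].
#' @export
read_script_yaml <- function(path) {
  v <- yaml::read_yaml(path)
  segs <- do.call(rbind, lapply(v$segments, function(s) {
    data.frame(kind = s$kind, duration_s = s$duration_s,
               cadence = s$cadence %||% NA_real_,
               amplitude = s$amplitude %||% NA_real_,
               noise_sd = s$noise_sd %||% NA_real_)
  }))
  activity_script(segs, seed = v$seed %||% 1L, start_s = v$start_s %||% 0,
                  anchor = as.POSIXct(v$anchor %||% "2000-01-01T00:00:00",
                                      tz = "UTC",
                                      tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                     "%Y-%m-%d %H:%M:%S")))
}
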