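#' Pulsed-tone schedule
#'
#' Timing of the pulsed tonal stimulus (default 1 s ON : 2 s OFF).
#'
#' @param onset_s Exposure onset in seconds from trial start.
#' @param period_s Pulse period (s), ON + OFF.
#' @param on_duration_s ON duration (s), must be `< period_s`.
#' @param n_pulses Number of pulses (>= 1).
#' @return A list of class `pulse_schedule`.
#' @export
pulse_schedule <- function(onset_s, period_s = 3, on_duration_s = 1,
                           n_pulses = 200) {
  stopifnot(on_duration_s < period_s, n_pulses >= 1)
  structure(list(onset_s = onset_s, period_s = period_s,
                 on_duration_s = on_duration_s, n_pulses = n_pulses),
            class = "pulse_schedule")
}

# internal: per-fish instantaneous speeds (frames x fish, m/s) and movement
# headings (degrees, atan2 of frame-to-frame displacement)
fish_speeds <- function(trial) {
  dx <- apply(trial$x, 2, diff); dy <- apply(trial$y, 2, diff)
  sp <- sqrt(dx^2 + dy^2) * trial$frame_rate
  rbind(sp[1, ], sp)
}

fish_headings <- function(trial) {
  dx <- apply(trial$x, 2, diff); dy <- apply(trial$y, 2, diff)
  h <- atan2(dy, dx) * 180 / pi
  rbind(h[1, ], h)
}

# internal: absolute angular difference folded to [0, 180]
ang_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Detect onset startle responses
#'
#' A fish is flagged as startling when, within the first `window_s` seconds
#' after stimulus onset, its instantaneous speed exceeds `speed_factor`
#' times its own pre-onset median speed while its movement heading changes
#' by at least `min_turn_deg` within `turn_window_s`. This is an automated
#' stand-in for visual startle scoring: a burst swim at an altered angle
#' relative to the pre-startle trajectory.
#'
#' @param trial A [trajectory_trial()] with at least `min_baseline_s`
#'   seconds of pre-onset footage.
#' @param window_s Detection window after onset (s, default 1).
#' @param speed_factor Speed threshold as a multiple of the fish's
#'   pre-onset median speed (default 4).
#' @param min_turn_deg Minimum heading change (degrees, default 45).
#' @param turn_window_s Window over which the heading change must occur
#'   (s, default 0.5).
#' @param min_baseline_s Required baseline length before onset (s).
#' @return List with `flags` (logical, length 5), `n_startled` (0-5) and
#'   `records` (data.frame: trial_id, fish_id, time_s, peak_speed,
#'   heading_change).
#' @export
detect_onset_startles <- function(trial, window_s = 1, speed_factor = 4,
                                  min_turn_deg = 45, turn_window_s = 0.5,
                                  min_baseline_s = 60) {
  stopifnot(inherits(trial, "trajectory_trial"))
  fr <- trial$frame_rate
  if (trial$onset_s < min_baseline_s)
    stop("missing baseline: need >= ", min_baseline_s, " s before onset",
         call. = FALSE)
  sp <- fish_speeds(trial); hd <- fish_headings(trial)
  on_f <- floor(trial$onset_s * fr) + 1L
  win_f <- on_f:min(nrow(sp), on_f + ceiling(window_s * fr) - 1L)
  base_f <- seq_len(on_f - 1L)
  tw <- max(1L, round(turn_window_s * fr))
  flags <- logical(5); recs <- list()
  for (i in 1:5) {
    base_med <- median(sp[base_f, i])
    thr <- speed_factor * base_med
    hit_frames <- win_f[sp[win_f, i] > thr]
    startled <- FALSE; best <- NULL
    for (n in hit_frames) {
      m <- (n + 1L):min(nrow(hd), n + tw)
      turn <- max(ang_diff(hd[m, i], hd[n, i]))
      if (turn >= min_turn_deg) {
        startled <- TRUE
        if (is.null(best) || sp[n, i] > best$peak_speed)
          best <- list(time_s = (n - 1) / fr, peak_speed = sp[n, i],
                       heading_change = turn)
      }
    }
    flags[i] <- startled
    if (startled)
      recs[[length(recs) + 1L]] <- data.frame(
        trial_id = trial$trial_id, fish_id = i, time_s = best$time_s,
        peak_speed = best$peak_speed, heading_change = best$heading_change)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(trial_id = character(), fish_id = integer(),
               time_s = numeric(), peak_speed = numeric(),
               heading_change = numeric())
  list(flags = flags, n_startled = sum(flags), records = records)
}

#' Count continuous startle responses against a pulse schedule
#'
#' Counts how many consecutive pulses, starting from pulse 1, drew at least
#' one startle within `[pulse_start, pulse_start + on_duration + grace_s]`;
#' the run stops at the first pulse with none. A run that starts at pulse 2
#' therefore scores 0 (counting is anchored at stimulus onset).
#'
#' @param startle_times Sorted numeric vector of startle times (s).
#' @param schedule A [pulse_schedule()].
#' @param grace_s Post-pulse grace window (s, default 0.5) during which a
#'   startle still counts toward the preceding pulse.
#' @return Integer count in `0:n_pulses`.
#' @export
continuous_startle_count <- function(startle_times, schedule, grace_s = 0.5) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  if (is.unsorted(startle_times)) stop("startle_times must be sorted", call. = FALSE)
  count <- 0L
  for (k in seq_len(schedule$n_pulses)) {
    p0 <- schedule$onset_s + (k - 1) * schedule$period_s
    p1 <- p0 + schedule$on_duration_s + grace_s
    if (any(startle_times >= p0 & startle_times <= p1)) count <- count + 1L
    else break
  }
  count
}

#' Write startle records and a group summary to CSV
#'
#' @param det Output of [detect_onset_startles()].
#' @param continuous_count Output of [continuous_startle_count()].
#' @param record_path,summary_path Output CSV paths (either may be `NULL`).
#' @param trial_id Trial identifier for the summary row.
#' @return Invisibly, the summary data.frame.
#' @export
write_startle_csv <- function(det, continuous_count, record_path = NULL,
                              summary_path = NULL, trial_id = NULL) {
  if (!is.null(record_path)) write.csv(det$records, record_path, row.names = FALSE)
  if (is.null(trial_id))
    trial_id <- if (nrow(det$records)) det$records$trial_id[1] else NA_character_
  summ <- data.frame(trial_id = trial_id, n_fish_startled = det$n_startled,
                     continuous_count = continuous_count)
  if (!is.null(summary_path)) write.csv(summ, summary_path, row.names = FALSE)
  invisible(summ)
}
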