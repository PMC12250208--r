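# Deterministic trajectory fixtures built in code.

# A calm trial: five fish drifting in formation at constant speed along x,
# constant body angles. No noise, no startles.
calm_trial <- function(duration_s = 70, onset_s = 60, frame_rate = 30,
                       drift_mps = 0.002, angles = c(-10, -5, 0, 5, 10)) {
  n <- duration_s * frame_rate
  base_x <- c(0.10, 0.25, 0.40, 0.55, 0.70)
  base_y <- c(0.10, 0.20, 0.15, 0.20, 0.10)
  drift <- (seq_len(n) - 1) * drift_mps / frame_rate
  x <- outer(drift, rep(1, 5)) + matrix(base_x, n, 5, byrow = TRUE)
  y <- matrix(base_y, n, 5, byrow = TRUE)
  ang <- matrix(angles, n, 5, byrow = TRUE)
  trajectory_trial("calm", "AMB-C", x, y, ang, frame_rate = frame_rate,
                   onset_s = onset_s, offset_s = duration_s)
}

# Inject a burst (fast dash with a sharp turn) into one fish of a calm
# trial, starting at `at_s`, lasting `dur_s`.
burst_trial <- function(fish = 3, at_s = 60.3, dur_s = 0.25, speed = 0.45,
                        turn_deg = -60, ...) {
  tr <- calm_trial(...)
  fr <- tr$frame_rate
  f0 <- floor(at_s * fr) + 1L
  nb <- round(dur_s * fr)
  idx <- f0:(f0 + nb - 1L)
  # pre-burst motion is along +x; dash at `turn_deg` from it
  th <- turn_deg * pi / 180
  step <- speed / fr
  dx <- cumsum(rep(step * cos(th), nb))
  dy <- cumsum(rep(step * sin(th), nb))
  tr$x[idx, fish] <- tr$x[idx, fish] + dx
  tr$y[idx, fish] <- tr$y[idx, fish] + dy
  # hold the displaced position afterwards (no teleport back)
  if (max(idx) < nrow(tr$x)) {
    after <- (max(idx) + 1L):nrow(tr$x)
    tr$x[after, fish] <- tr$x[after, fish] + dx[nb]
    tr$y[after, fish] <- tr$y[after, fish] + dy[nb]
  }
  stopifnot(all(tr$x >= 0 & tr$x <= tr$tank[1]),
            all(tr$y >= 0 & tr$y <= tr$tank[2]))
  tr
}

# Random 5-fish frame within the tank.
random_frame <- function() cbind(runif(5, 0, 0.86), runif(5, 0, 0.308))
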