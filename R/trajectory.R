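#' Construct a trajectory trial
#'
#' Container for one trial: per-frame positions (m) and body-axis angles
#' (degrees) of a group of five fish filmed from above, plus stimulus timing.
#'
#' @param trial_id Character scalar identifying the trial.
#' @param treatment One of [TREATMENTS].
#' @param x,y Numeric matrices, frames x fish, positions in metres.
#' @param angle Numeric matrix, frames x fish, body-axis angle in degrees
#'   within \[-90, 90\] (axial convention: head-to-tail line against a
#'   horizontal reference).
#' @param frame_rate Frames per second (default 30).
#' @param onset_s,offset_s Stimulus window in seconds from trial start.
#' @param tank Tank dimensions `c(length, breadth)` in metres.
#'
#' @return An object of class `trajectory_trial`.
#' @export
trajectory_trial <- function(trial_id, treatment, x, y, angle,
                             frame_rate = 30, onset_s, offset_s,
                             tank = TANK_DEFAULT) {
  treatment <- match.arg(treatment, TREATMENTS)
  x <- as.matrix(x); y <- as.matrix(y); angle <- as.matrix(angle)
  if (ncol(x) != 5L || ncol(y) != 5L || ncol(angle) != 5L)
    stop("a trial holds exactly 5 fish", call. = FALSE)
  if (nrow(x) != nrow(y) || nrow(x) != nrow(angle))
    stop("frame count differs between position and angle tables", call. = FALSE)
  if (anyNA(x) || anyNA(y) || anyNA(angle))
    stop("incomplete frame: missing fish position or angle", call. = FALSE)
  if (any(x < -1e-9) || any(x > tank[1] + 1e-9) ||
      any(y < -1e-9) || any(y > tank[2] + 1e-9))
    stop("positions outside tank bounds", call. = FALSE)
  if (any(angle < -90 - 1e-9) || any(angle > 90 + 1e-9))
    stop("angles outside [-90, 90] degrees", call. = FALSE)
  duration <- nrow(x) / frame_rate
  if (!(onset_s < offset_s && offset_s <= duration + 1e-9))
    stop("require onset_s < offset_s <= trial duration", call. = FALSE)
  structure(list(trial_id = as.character(trial_id), treatment = treatment,
                 x = x, y = y, angle = angle, frame_rate = frame_rate,
                 onset_s = onset_s, offset_s = offset_s, tank = tank),
            class = "trajectory_trial")
}

#' @export
print.trajectory_trial <- function(x, ...) {
  cat("<trajectory_trial> ", x$trial_id, " [", x$treatment, "]\n", sep = "")
  cat(sprintf("  %d frames @ %g fps (%.1f s), 5 fish, tone %g-%g s\n",
              nrow(x$x), x$frame_rate, nrow(x$x) / x$frame_rate,
              x$onset_s, x$offset_s))
  invisible(x)
}

#' Write / read trajectory trials as tidy CSV with a YAML sidecar
#'
#' One row per frame x fish (`trial_id, frame, fish_id, x_m, y_m,
#' angle_deg`); treatment, frame rate, stimulus window and tank size go to
#' `<path>.yaml`.
#'
#' @param trial A `trajectory_trial`.
#' @param path CSV file path; the sidecar is `paste0(path, ".yaml")`.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a `trajectory_trial`.
#' @export
write_trajectory_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trajectory_trial"))
  nf <- nrow(trial$x)
  df <- data.frame(
    trial_id = trial$trial_id,
    frame = rep(seq_len(nf), times = 5L),
    fish_id = rep(1:5, each = nf),
    x_m = as.vector(trial$x), y_m = as.vector(trial$y),
    angle_deg = as.vector(trial$angle))
  write.csv(df, path, row.names = FALSE)
  meta <- list(trial_id = trial$trial_id, treatment = trial$treatment,
               frame_rate = trial$frame_rate, onset_s = trial$onset_s,
               offset_s = trial$offset_s,
               tank_m = as.numeric(trial$tank))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param path CSV file written by [write_trajectory_csv()].
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  df <- df[order(df$fish_id, df$frame), ]
  nf <- max(df$frame)
  shape <- function(v) matrix(v, nrow = nf, ncol = 5L)
  trajectory_trial(meta$trial_id, meta$treatment,
                   shape(df$x_m), shape(df$y_m), shape(df$angle_deg),
                   frame_rate = meta$frame_rate,
                   onset_s = meta$onset_s, offset_s = meta$offset_s,
                   tank = as.numeric(meta$tank_m))
}
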