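#' Shoal centre of one frame
#'
#' Arithmetic mean of the five fish positions, component-wise: the "mean
#' shoal centre" whose frame-to-frame displacement defines group swimming
#' speed.
#'
#' @param positions 5 x 2 numeric matrix of (x, y) positions in metres.
#' @return Numeric length-2 vector `c(x_c, y_c)` in metres.
#' @export
shoal_centre <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) != 5L || ncol(positions) != 2L || !all(is.finite(positions)))
    stop("incomplete frame: need 5 finite (x, y) pairs", call. = FALSE)
  colMeans(positions)
}

#' Group swimming speed from a shoal-centre track
#'
#' Euclidean displacement of the shoal centre between consecutive frames
#' times the frame rate. The first frame, which has no predecessor, copies
#' the second frame's value so the series keeps the frame count.
#'
#' @param centre_series Frames x 2 matrix of shoal-centre positions (m).
#' @param frame_rate Frames per second.
#' @return Per-frame speed in m/s (length = number of frames).
#' @export
group_speed <- function(centre_series, frame_rate = 30) {
  cs <- as.matrix(centre_series)
  if (nrow(cs) < 2L)
    stop("insufficient data: speed needs at least 2 frames", call. = FALSE)
  d <- sqrt(diff(cs[, 1])^2 + diff(cs[, 2])^2) * frame_rate
  c(d[1], d)
}

#' Inter-individual distance (group cohesion) of one frame
#'
#' Combined positional spread of the group:
#' \eqn{\sqrt{sd_x^2 + sd_y^2}} with population standard deviations
#' (divisor n) across the five fish. Algebraically this equals the
#' root-mean-square distance of the fish from the shoal centre. Set
#' `method = "mean_dist"` for the plain mean Euclidean distance from the
#' centre instead.
#'
#' @inheritParams shoal_centre
#' @param method `"sd"` (default, combined x/y population SD) or
#'   `"mean_dist"` (mean distance to the shoal centre).
#' @return Distance in metres (>= 0).
#' @export
inter_individual_distance <- function(positions, method = c("sd", "mean_dist")) {
  method <- match.arg(method)
  positions <- as.matrix(positions)
  if (nrow(positions) != 5L || ncol(positions) != 2L || !all(is.finite(positions)))
    stop("incomplete frame: need 5 finite (x, y) pairs", call. = FALSE)
  ctr <- colMeans(positions)
  if (method == "mean_dist")
    return(mean(sqrt((positions[, 1] - ctr[1])^2 + (positions[, 2] - ctr[2])^2)))
  vx <- mean((positions[, 1] - ctr[1])^2)
  vy <- mean((positions[, 2] - ctr[2])^2)
  sqrt(vx + vy)
}

#' Group alignment of one frame
#'
#' Standard deviation of the five body-axis angles (degrees, axial
#' convention in \[-90, 90\]); lower values mean stronger alignment. Angles
#' are treated as linear quantities; when any pair of angles differs by
#' more than 90 degrees the axial fold makes the linear SD unreliable and a
#' warning is emitted.
#'
#' @param angles Numeric vector of 5 angles in degrees, within \[-90, 90\].
#' @param divisor `"n-1"` (sample SD, default) or `"n"` (population SD).
#' @return Angular standard deviation in degrees (0 to <= 90).
#' @export
alignment <- function(angles, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  if (length(angles) != 5L || !all(is.finite(angles)))
    stop("incomplete frame: need 5 finite angles", call. = FALSE)
  if (any(angles < -90 - 1e-9) || any(angles > 90 + 1e-9))
    stop("angle out of [-90, 90] degrees", call. = FALSE)
  if (max(angles) - min(angles) > 90)
    warning("angle pair differs by > 90 degrees: axial wrap-around may inflate the linear SD")
  v <- sum((angles - mean(angles))^2) / if (divisor == "n-1") 4 else 5
  sqrt(v)
}

#' Per-second group metric series for a trial
#'
#' Computes group speed, inter-individual distance and alignment for every
#' frame, then averages (mean) into consecutive 1-s bins aligned to trial
#' start. A trailing partial bin is discarded.
#'
#' @param trial A [trajectory_trial()].
#' @param iid_method Passed to [inter_individual_distance()].
#' @return A data.frame of class `group_metric_series` with columns
#'   `time_s` (bin centre-left edge, s), `speed` (m/s), `iid` (m),
#'   `alignment` (degrees).
#' @export
metric_series <- function(trial, iid_method = "sd") {
  stopifnot(inherits(trial, "trajectory_trial"))
  nf <- nrow(trial$x)
  ctr <- cbind(rowMeans(trial$x), rowMeans(trial$y))
  speed <- group_speed(ctr, trial$frame_rate)
  # population SDs across the 5 fish, vectorised over frames
  vx <- rowMeans((trial$x - ctr[, 1])^2)
  vy <- rowMeans((trial$y - ctr[, 2])^2)
  iid <- if (iid_method == "sd") sqrt(vx + vy) else
    rowMeans(sqrt((trial$x - ctr[, 1])^2 + (trial$y - ctr[, 2])^2))
  am <- rowMeans(trial$angle)
  algn <- sqrt(rowSums((trial$angle - am)^2) / 4)
  fr <- trial$frame_rate
  n_bins <- floor(nf / fr)
  if (n_bins < 1L) stop("trial shorter than 1 s", call. = FALSE)
  idx <- rep(seq_len(n_bins), each = fr)
  keep <- seq_len(n_bins * fr)
  agg <- function(v) as.numeric(tapply(v[keep], idx, mean))
  out <- data.frame(time_s = seq_len(n_bins) - 1,
                    speed = agg(speed), iid = agg(iid), alignment = agg(algn))
  class(out) <- c("group_metric_series", "data.frame")
  out
}

#' Blocked median / MAD summary of a 1-s metric series
#'
#' Splits a 1-s series into consecutive non-overlapping windows (default
#' 30 s) and returns the median and raw median absolute deviation of each.
#' At most `n_blocks` windows are summarised; the series must contain at
#' least one full window.
#'
#' @param series Numeric vector of 1-s metric values.
#' @param window Window length in seconds (default 30).
#' @param n_blocks Maximum number of blocks (default 21, covering a 10-min
#'   exposure plus the onset-containing window).
#' @return A data.frame of class `blocked_series`: `block_index`,
#'   `block_start_s`, `median`, `mad` (unscaled MAD).
#' @export
block_summarise <- function(series, window = 30, n_blocks = 21) {
  series <- as.numeric(series)
  if (length(series) < window)
    stop("series shorter than one window", call. = FALSE)
  nb <- min(n_blocks, floor(length(series) / window))
  out <- data.frame(block_index = seq_len(nb),
                    block_start_s = (seq_len(nb) - 1) * window,
                    median = NA_real_, mad = NA_real_)
  for (b in seq_len(nb)) {
    v <- series[((b - 1) * window + 1):(b * window)]
    if (!length(v) || anyNA(v)) stop("empty block", call. = FALSE)
    out$median[b] <- median(v)
    out$mad[b] <- median(abs(v - median(v)))
  }
  class(out) <- c("blocked_series", "data.frame")
  out
}

#' Fraction of blocks deviating from a control baseline
#'
#' A block deviates when the treatment's `median +/- mad` interval and the
#' control's are disjoint (no overlap). Returns the deviating fraction and
#' the signed direction per block.
#'
#' @param treatment_blocks,control_blocks [block_summarise()] outputs with
#'   equal block counts.
#' @return List with `fraction` (deviating blocks / total, in \[0, 1\]) and
#'   `direction` (character per block: `"above"`, `"below"`, `"none"`).
#' @export
deviation_fraction <- function(treatment_blocks, control_blocks) {
  if (nrow(treatment_blocks) != nrow(control_blocks))
    stop("mismatched block counts", call. = FALSE)
  t_lo <- treatment_blocks$median - treatment_blocks$mad
  t_hi <- treatment_blocks$median + treatment_blocks$mad
  c_lo <- control_blocks$median - control_blocks$mad
  c_hi <- control_blocks$median + control_blocks$mad
  direction <- ifelse(t_lo > c_hi, "above", ifelse(t_hi < c_lo, "below", "none"))
  list(fraction = mean(direction != "none"), direction = direction)
}

#' Write a 1-s metric series or blocked summary to CSV
#'
#' @param x A `group_metric_series` or `blocked_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
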