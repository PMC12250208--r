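#' Signal-detection contingency table
#'
#' Counts of the four signal-response outcomes for one treatment at one
#' behavioural scale.
#'
#' @param hits,misses,false_alarms,correct_non_responses Non-negative
#'   integer counts. Signal trials = hits + misses; noise trials =
#'   false alarms + correct non-responses.
#' @return A list of class `contingency_table` with the four counts plus
#'   `n_signal` and `n_noise`.
#' @export
contingency_table <- function(hits, misses, false_alarms,
                              correct_non_responses) {
  cnt <- c(hits, misses, false_alarms, correct_non_responses)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers", call. = FALSE)
  n_signal <- hits + misses
  n_noise <- false_alarms + correct_non_responses
  if (n_signal < 1L || n_noise < 1L)
    stop("need at least one signal and one noise trial", call. = FALSE)
  structure(list(hits = hits, misses = misses, false_alarms = false_alarms,
                 correct_non_responses = correct_non_responses,
                 n_signal = n_signal, n_noise = n_noise),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>\n")
  m <- matrix(c(x$hits, x$false_alarms, x$misses, x$correct_non_responses),
              2, 2, dimnames = list(c("signal", "noise"), c("yes", "no")))
  print(m)
  invisible(x)
}

#' Hit and false-alarm rates with extreme-rate corrections
#'
#' Raw rates `hits / n_signal` and `false_alarms / n_noise`; a rate of
#' exactly 0 is replaced by `1/(2N)` and a rate of exactly 1 by
#' `1 - 1/(2N)` (N = the relevant trial count), so that the normal-quantile
#' transform stays finite. Interior rates are left untouched.
#'
#' @param table A [contingency_table()].
#' @return List: `hr`, `far` (both in (0, 1)), and logical
#'   `hr_corrected`, `far_corrected`.
#' @export
corrected_rates <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  fix <- function(p, N) {
    if (p == 0) list(p = 1 / (2 * N), corrected = TRUE)
    else if (p == 1) list(p = 1 - 1 / (2 * N), corrected = TRUE)
    else list(p = p, corrected = FALSE)
  }
  h <- fix(table$hits / table$n_signal, table$n_signal)
  f <- fix(table$false_alarms / table$n_noise, table$n_noise)
  list(hr = h$p, far = f$p, hr_corrected = h$corrected,
       far_corrected = f$corrected)
}

#' Discriminability d'
#'
#' `d' = z(HR) - z(FAR)` with z the inverse standard-normal distribution
#' function: the separation, in standard-deviation units, of the internal
#' signal and noise distributions.
#'
#' @param hr,far Hit and false-alarm rates, strictly inside (0, 1); apply
#'   [corrected_rates()] first when counts sit at the 0/1 boundary.
#' @return d' in standard-deviation units.
#' @export
dprime <- function(hr, far) {
  check_rates(hr, far)
  qnorm(hr) - qnorm(far)
}

#' Response criterion c
#'
#' `c = -(z(HR) + z(FAR)) / 2`: the decision-rule bias. Zero is unbiased;
#' positive values indicate a conservative ("no"-leaning) observer,
#' negative values a liberal ("yes"-leaning) one.
#'
#' @inheritParams dprime
#' @return c in standard-deviation units.
#' @export
criterion <- function(hr, far) {
  check_rates(hr, far)
  -(qnorm(hr) + qnorm(far)) / 2
}

check_rates <- function(hr, far) {
  if (any(hr <= 0 | hr >= 1) || any(far <= 0 | far >= 1))
    stop("rates must lie strictly inside (0, 1); apply corrected_rates() to boundary counts",
         call. = FALSE)
  invisible(TRUE)
}

#' Full SDT summary of a contingency table
#'
#' Applies the boundary corrections and returns rates, d' and c as one
#' classed result.
#'
#' @param table A [contingency_table()].
#' @param label Optional treatment / scale label.
#' @return A list of class `sdt_result`: `label`, `hr`, `far`, `dprime`,
#'   `criterion`, `hr_corrected`, `far_corrected`, `table`.
#' @export
sdt <- function(table, label = NA_character_) {
  r <- corrected_rates(table)
  structure(list(label = label, hr = r$hr, far = r$far,
                 dprime = dprime(r$hr, r$far),
                 criterion = criterion(r$hr, r$far),
                 hr_corrected = r$hr_corrected, far_corrected = r$far_corrected,
                 table = table),
            class = "sdt_result")
}

#' @export
print.sdt_result <- function(x, ...) {
  cat(sprintf("<sdt_result> %s: HR = %.3f%s, FAR = %.3f%s, d' = %.2f, c = %.2f\n",
              x$label, x$hr, if (x$hr_corrected) "*" else "",
              x$far, if (x$far_corrected) "*" else "",
              x$dprime, x$criterion))
  if (x$hr_corrected || x$far_corrected)
    cat("  (* boundary rate corrected by 1/(2N))\n")
  invisible(x)
}

#' ROC points and reference iso-curves
#'
#' Builds plot-ready receiver-operating-characteristic artifacts: the
#' (FAR, HR) point per result, iso-discriminability curves
#' `HR = Phi(d + z(FAR))` and iso-criterion curves
#' `HR = Phi(-2c - z(FAR))`.
#'
#' @param results List of [sdt()] results (may be empty).
#' @param iso_d d' values for reference curves (default 0:3).
#' @param iso_c c values for reference curves.
#' @param far_grid FAR abscissa for the curves.
#' @return A list of class `roc_artifacts`: `points` (data.frame: label,
#'   far, hr, dprime, criterion), `iso_d` and `iso_c` (long data.frames:
#'   level, far, hr).
#' @export
roc_artifacts <- function(results = list(), iso_d = c(0, 1, 2, 3),
                          iso_c = c(-1, -0.5, 0, 0.5, 1),
                          far_grid = seq(0.001, 0.999, by = 0.001)) {
  pts <- if (length(results)) data.frame(
    label = vapply(results, `[[`, "", "label"),
    far = vapply(results, `[[`, 1, "far"),
    hr = vapply(results, `[[`, 1, "hr"),
    dprime = vapply(results, `[[`, 1, "dprime"),
    criterion = vapply(results, `[[`, 1, "criterion"))
  else data.frame(label = character(), far = numeric(), hr = numeric(),
                  dprime = numeric(), criterion = numeric())
  z <- qnorm(far_grid)
  iso_d_df <- do.call(rbind, lapply(iso_d, function(d)
    data.frame(level = d, far = far_grid, hr = pnorm(d + z))))
  iso_c_df <- do.call(rbind, lapply(iso_c, function(cc)
    data.frame(level = cc, far = far_grid, hr = pnorm(-2 * cc - z))))
  structure(list(points = pts, iso_d = iso_d_df, iso_c = iso_c_df),
            class = "roc_artifacts")
}

#' @export
plot.roc_artifacts <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False-alarm rate", ylab = "Hit rate",
                 main = "ROC", asp = 1, ...)
  for (d in unique(x$iso_d$level)) {
    s <- x$iso_d[x$iso_d$level == d, ]
    graphics::lines(s$far, s$hr, col = "grey70")
  }
  for (cc in unique(x$iso_c$level)) {
    s <- x$iso_c[x$iso_c$level == cc, ]
    graphics::lines(s$far, s$hr, col = "grey40", lty = 2)
  }
  if (nrow(x$points))
    graphics::points(x$points$far, x$points$hr, pch = 19)
  invisible(x)
}

#' Write an SDT summary table to CSV
#'
#' @param results List of [sdt()] results.
#' @param scale Character label (`"coarse"` or `"fine"`), recycled.
#' @param path Optional output CSV path.
#' @return The summary data.frame (invisibly when written to file).
#' @export
sdt_summary <- function(results, scale = NA_character_, path = NULL) {
  df <- data.frame(
    treatment = vapply(results, `[[`, "", "label"),
    scale = scale,
    hits = vapply(results, function(r) r$table$hits, 1),
    misses = vapply(results, function(r) r$table$misses, 1),
    fas = vapply(results, function(r) r$table$false_alarms, 1),
    cnrs = vapply(results, function(r) r$table$correct_non_responses, 1),
    hr = vapply(results, `[[`, 1, "hr"),
    far = vapply(results, `[[`, 1, "far"),
    dprime = vapply(results, `[[`, 1, "dprime"),
    criterion = vapply(results, `[[`, 1, "criterion"))
  if (!is.null(path)) { write.csv(df, path, row.names = FALSE); return(invisible(df)) }
  df
}
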