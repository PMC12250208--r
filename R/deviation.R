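#' GLS slope with 95% confidence interval
#'
#' Fits the linear trend `y = b0 + b1 * t` to a 1-s metric series. With
#' `corr = "ar1"` (default) the errors follow a first-order autoregressive
#' process and the model is estimated by (restricted) maximum likelihood
#' via [nlme::gls()]; with `corr = "none"` the fit is ordinary least
#' squares. The 95% interval is `b1 +/- t(0.975, n - 2) * se`.
#'
#' A perfectly linear or constant series (residual variance ~ 0) is handled
#' as a degenerate exact fit with `se = 0`.
#'
#' @param y Numeric metric series (>= 10 observations).
#' @param t Strictly increasing time vector (s), same length as `y`.
#' @param corr Error correlation structure: `"ar1"` or `"none"`.
#' @return A list of class `slope_ci`: `slope`, `se`, `ci_lo`, `ci_hi`
#'   (all in metric units per second), `ar1` (estimated lag-1 correlation,
#'   0 when `corr = "none"`), `n_obs`, and the intercept `b0`.
#' @export
gls_slope_ci <- function(y, t, corr = c("ar1", "none")) {
  corr <- match.arg(corr)
  y <- as.numeric(y); t <- as.numeric(t)
  n <- length(y)
  if (n < 10L) stop("need >= 10 observations", call. = FALSE)
  if (length(t) != n || any(diff(t) <= 0))
    stop("t must be strictly increasing and match y", call. = FALSE)

  # degenerate exact fits: constant series or noiseless line
  X <- cbind(1, t)
  ols <- stats::lm.fit(X, y)
  res_sd <- sqrt(sum(ols$residuals^2) / (n - 2))
  scale <- max(abs(y), 1e-12)
  if (res_sd < 1e-10 * scale) {
    b <- ols$coefficients
    return(new_slope_ci(b[2], 0, b[2], b[2], 0, n, b[1]))
  }

  if (corr == "none") {
    sm <- summary(stats::lm(y ~ t))
    slope <- sm$coefficients[2, 1]; se <- sm$coefficients[2, 2]
    b0 <- sm$coefficients[1, 1]; phi <- 0
  } else {
    df <- data.frame(y = y, t = t)
    fit <- tryCatch(
      nlme::gls(y ~ t, data = df, correlation = nlme::corAR1(form = ~1),
                method = "REML"),
      error = function(e) stop("GLS estimation failed: ", conditionMessage(e),
                               call. = FALSE))
    tt <- summary(fit)$tTable
    slope <- tt[2, 1]; se <- tt[2, 2]; b0 <- tt[1, 1]
    phi <- as.numeric(coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  }
  half <- qt(0.975, n - 2) * se
  new_slope_ci(slope, se, slope - half, slope + half, phi, n, b0)
}

new_slope_ci <- function(slope, se, ci_lo, ci_hi, ar1, n_obs, intercept) {
  structure(list(slope = unname(slope), se = unname(se),
                 ci_lo = unname(ci_lo), ci_hi = unname(ci_hi),
                 ar1 = unname(ar1), n_obs = n_obs,
                 intercept = unname(intercept)),
            class = "slope_ci")
}

#' @export
print.slope_ci <- function(x, ...) {
  cat(sprintf("<slope_ci> y = %.4g + %.4g t; +/- s.e. = %.3g; CI [%.4g; %.4g]; AR1 = %.3f; n = %d\n",
              x$intercept, x$slope, x$se, x$ci_lo, x$ci_hi, x$ar1, x$n_obs))
  invisible(x)
}

#' Normative fit: pooled control-group slope
#'
#' The control reference ("normative fit") against which individual trial
#' slopes are judged: a GLS fit to the point-wise mean of the control
#' trials' metric series. With `pooling = "ivw"` an inverse-variance
#' weighted pool of the per-trial slopes is returned instead.
#'
#' @param control_series List (length >= 2) of numeric metric series on a
#'   common time base.
#' @param t Time vector (s) shared by all series.
#' @param corr Passed to [gls_slope_ci()].
#' @param pooling `"mean_series"` (default) or `"ivw"`.
#' @return A `slope_ci`.
#' @export
normative_fit <- function(control_series, t, corr = "ar1",
                          pooling = c("mean_series", "ivw")) {
  pooling <- match.arg(pooling)
  if (!is.list(control_series) || length(control_series) < 2L)
    stop("need at least 2 control trials", call. = FALSE)
  len <- unique(vapply(control_series, length, 1L))
  if (length(len) != 1L || len != length(t))
    stop("control series must share the common time base", call. = FALSE)
  if (pooling == "mean_series") {
    ybar <- rowMeans(do.call(cbind, control_series))
    return(gls_slope_ci(ybar, t, corr = corr))
  }
  fits <- lapply(control_series, gls_slope_ci, t = t, corr = corr)
  w <- vapply(fits, function(f) 1 / f$se^2, 1)
  slope <- sum(w * vapply(fits, `[[`, 1, "slope")) / sum(w)
  se <- sqrt(1 / sum(w))
  n <- len
  half <- qt(0.975, n - 2) * se
  new_slope_ci(slope, se, slope - half, slope + half,
               mean(vapply(fits, `[[`, 1, "ar1")), n,
               mean(vapply(fits, `[[`, 1, "intercept")))
}

#' Classify a trial against the normative fit
#'
#' A trial deviates when its slope CI and the control (normative) CI are
#' disjoint: upper trial bound below the control lower bound, or lower
#' trial bound above the control upper bound. Deviation in either direction
#' scores as a response; the outcome then follows the standard
#' signal-detection contingency: deviated & signal -> hit, not deviated &
#' signal -> miss, deviated & no signal -> false alarm, otherwise correct
#' non-response.
#'
#' @param trial_ci,control_ci `slope_ci` objects.
#' @param signal_present Logical: was the tonal stimulus present?
#' @param trial_id Optional identifier carried into the result.
#' @return A list of class `trial_classification`: `trial_id`,
#'   `signal_present`, `deviated`, `outcome`, `direction`.
#' @export
classify_trial <- function(trial_ci, control_ci, signal_present,
                           trial_id = NA_character_) {
  stopifnot(inherits(trial_ci, "slope_ci"), inherits(control_ci, "slope_ci"))
  below <- trial_ci$ci_hi < control_ci$ci_lo
  above <- trial_ci$ci_lo > control_ci$ci_hi
  deviated <- below || above
  outcome <- if (signal_present) {
    if (deviated) "hit" else "miss"
  } else {
    if (deviated) "false_alarm" else "correct_non_response"
  }
  structure(list(trial_id = trial_id, signal_present = signal_present,
                 deviated = deviated, outcome = outcome,
                 direction = if (above) "above" else if (below) "below" else "none"),
            class = "trial_classification")
}

#' Tally classifications into a contingency table
#'
#' @param classifications Non-empty list of [classify_trial()] results.
#' @return A [contingency_table()].
#' @export
contingency_from_classifications <- function(classifications) {
  if (!length(classifications)) stop("no classifications to tally", call. = FALSE)
  oc <- vapply(classifications, `[[`, "", "outcome")
  contingency_table(hits = sum(oc == "hit"), misses = sum(oc == "miss"),
                    false_alarms = sum(oc == "false_alarm"),
                    correct_non_responses = sum(oc == "correct_non_response"))
}

#' Per-trial classification report
#'
#' Flat CSV-ready table mirroring the per-trial supplementary layout:
#' trial, treatment, slope, CI bounds, deviation flag and outcome.
#'
#' @param classifications List of `trial_classification`s.
#' @param cis List of the matching trial `slope_ci`s.
#' @param treatments Character vector of treatment labels.
#' @param path Optional CSV output path.
#' @return data.frame, invisibly written to `path` when given.
#' @export
classification_report <- function(classifications, cis, treatments,
                                  path = NULL) {
  df <- data.frame(
    trial_id = vapply(classifications, `[[`, "", "trial_id"),
    treatment = treatments,
    slope = vapply(cis, `[[`, 1, "slope"),
    se = vapply(cis, `[[`, 1, "se"),
    ci_lo = vapply(cis, `[[`, 1, "ci_lo"),
    ci_hi = vapply(cis, `[[`, 1, "ci_hi"),
    deviated = vapply(classifications, `[[`, TRUE, "deviated"),
    outcome = vapply(classifications, `[[`, "", "outcome"),
    direction = vapply(classifications, `[[`, "", "direction"))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  invisible(df)
}
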