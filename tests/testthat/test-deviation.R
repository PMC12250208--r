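test_that("noiseless and constant series give exact degenerate fits", {
  t <- 0:599
  y <- 0.3 - 1e-5 * t
  ci <- gls_slope_ci(y, t)
  expect_equal(ci$slope, -1e-5, tolerance = 1e-10)
  expect_lt(ci$ci_hi - ci$ci_lo, 1e-12)

  cc <- gls_slope_ci(rep(0.25, 100), 1:100)
  expect_equal(cc$slope, 0)
  expect_equal(cc$se, 0)
})

test_that("with corr = none the slope and CI match the OLS closed form", {
  set.seed(31)
  t <- seq(0, 98, by = 2)
  y <- 0.2 + 3e-4 * t + rnorm(length(t), 0, 0.05)
  ci <- gls_slope_ci(y, t, corr = "none")
  # hand-coded closed form
  n <- length(t)
  sxx <- sum((t - mean(t))^2)
  b1 <- sum((t - mean(t)) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * mean(t)
  s2 <- sum((y - b0 - b1 * t)^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  expect_equal(ci$slope, b1, tolerance = 1e-8)
  expect_equal(ci$se, se, tolerance = 1e-8)
  expect_equal(ci$ci_lo, b1 - qt(0.975, n - 2) * se, tolerance = 1e-8)
  expect_equal(ci$ci_hi, b1 + qt(0.975, n - 2) * se, tolerance = 1e-8)
  expect_equal(ci$ar1, 0)
})

test_that("input contracts are enforced", {
  expect_error(gls_slope_ci(rnorm(5), 1:5), ">= 10")
  expect_error(gls_slope_ci(rnorm(10), c(1:5, 5:1)), "increasing")
})

test_that("the AR(1) fit recovers the autocorrelation and covers the slope", {
  set.seed(77)
  t <- 1:400
  phi <- 0.6; b1 <- 5e-4
  hits <- 0
  for (r in 1:20) {
    y <- 0.1 + b1 * t + as.numeric(arima.sim(list(ar = phi), 400, sd = 0.05))
    ci <- gls_slope_ci(y, t, corr = "ar1")
    if (r == 1) expect_lt(abs(ci$ar1 - phi), 0.2)
    hits <- hits + (ci$ci_lo <= b1 && b1 <= ci$ci_hi)
  }
  expect_gte(hits, 16)  # ~95% nominal coverage
})

test_that("the normative fit pools control trials", {
  t <- 0:199
  base <- 0.3 + 2e-5 * t
  same <- list(base, base, base)
  nf <- normative_fit(same, t)
  single <- gls_slope_ci(base, t)
  expect_equal(nf$slope, single$slope, tolerance = 1e-10)
  expect_equal(nf$se, single$se, tolerance = 1e-10)

  set.seed(12)
  noisy <- lapply(1:6, function(i) base + rnorm(200, 0, 0.03))
  nf2 <- normative_fit(noisy, t, corr = "none")
  singles <- lapply(noisy, gls_slope_ci, t = t, corr = "none")
  expect_lt(abs(nf2$slope - 2e-5), 3 * nf2$se + 1e-5)
  expect_lt(nf2$se, median(vapply(singles, `[[`, 1, "se")))

  expect_error(normative_fit(list(base), t), "at least 2")

  # report round trip carries the regression-line fields
  out <- capture.output(print(nf2))
  expect_match(out, "y = .* t; \\+/- s\\.e\\. = .*; CI \\[")
})

test_that("trials are classified by CI disjointness against the control CI", {
  ctl <- shoalsdt:::new_slope_ci(3.84e-5, 2.04e-5, -1.70e-6, 7.84e-5, 0.2, 600, 0.217)
  up <- shoalsdt:::new_slope_ci(1.5e-4, 2e-5, 1.0e-4, 2.0e-4, 0.2, 600, 0.2)
  cl <- classify_trial(up, ctl, signal_present = TRUE, trial_id = "t01")
  expect_true(cl$deviated)
  expect_equal(cl$direction, "above")
  expect_equal(cl$outcome, "hit")

  same <- classify_trial(ctl, ctl, signal_present = TRUE)
  expect_false(same$deviated)
  expect_equal(same$outcome, "miss")
  expect_equal(classify_trial(ctl, ctl, FALSE)$outcome, "correct_non_response")

  dn <- shoalsdt:::new_slope_ci(-3e-5, 1e-5, -5e-5, -1e-5, 0.2, 600, 0.3)
  cl2 <- classify_trial(dn, ctl, signal_present = FALSE)
  expect_true(cl2$deviated)
  expect_equal(cl2$direction, "below")
  expect_equal(cl2$outcome, "false_alarm")
})

test_that("widening the control CI never creates a deviation", {
  set.seed(8)
  mk <- function(lo, hi) shoalsdt:::new_slope_ci((lo + hi) / 2, (hi - lo) / 4,
                                                 lo, hi, 0, 100, 0)
  for (r in 1:200) {
    tlo <- rnorm(1); thi <- tlo + runif(1)
    clo <- rnorm(1); chi <- clo + runif(1)
    wide <- mk(clo - runif(1), chi + runif(1))
    d1 <- classify_trial(mk(tlo, thi), mk(clo, chi), TRUE)$deviated
    d2 <- classify_trial(mk(tlo, thi), wide, TRUE)$deviated
    expect_true(!d2 || d1)  # wide deviation implies narrow deviation
  }
})

test_that("contingency tallies match a manual enumeration", {
  mk <- function(outcome, sp) structure(
    list(trial_id = "x", signal_present = sp,
         deviated = outcome %in% c("hit", "false_alarm"),
         outcome = outcome, direction = "none"),
    class = "trial_classification")
  cls <- c(replicate(10, mk("hit", TRUE), simplify = FALSE),
           replicate(10, mk("correct_non_response", FALSE), simplify = FALSE))
  tab <- contingency_from_classifications(cls)
  expect_equal(c(tab$hits, tab$misses, tab$false_alarms, tab$correct_non_responses),
               c(10, 0, 0, 10))

  set.seed(3)
  ocs <- sample(c("hit", "miss", "false_alarm", "correct_non_response"),
                37, replace = TRUE)
  cls2 <- lapply(ocs, function(o) mk(o, o %in% c("hit", "miss")))
  tab2 <- contingency_from_classifications(cls2)
  ref <- table(factor(ocs, levels = c("hit", "miss", "false_alarm",
                                      "correct_non_response")))
  expect_equal(c(tab2$hits, tab2$misses, tab2$false_alarms,
                 tab2$correct_non_responses), as.numeric(ref))
  expect_equal(tab2$n_signal, tab2$hits + tab2$misses)

  expect_error(contingency_from_classifications(list()), "no classifications")
})
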