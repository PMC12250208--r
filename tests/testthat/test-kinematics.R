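test_that("shoal centre is the component-wise mean of the five positions", {
  p <- matrix(c(0.10, 0.20), 5, 2, byrow = TRUE)
  expect_equal(shoal_centre(p), c(0.10, 0.20))

  p <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5))
  expect_equal(shoal_centre(p), c(0.5, 0.5))

  set.seed(1)
  for (r in 1:20) {
    p <- random_frame()
    # independent per-coordinate summation oracle
    expect_equal(shoal_centre(p),
                 c(sum(p[, 1]) / 5, sum(p[, 2]) / 5), tolerance = 1e-12)
  }

  p[2, 1] <- NA
  expect_error(shoal_centre(p), "incomplete")
  expect_error(shoal_centre(random_frame()[1:4, ]), "incomplete")
})

test_that("group speed is centre displacement times frame rate, first frame padded", {
  ctr <- matrix(c(0.4, 0.15), 300, 2, byrow = TRUE)
  expect_equal(group_speed(ctr, 30), rep(0, 300))

  n <- 150
  ctr <- cbind(0.1 + (seq_len(n) - 1) * 0.05 / 30, rep(0.15, n))
  sp <- group_speed(ctr, 30)
  expect_equal(sp, rep(0.05, n), tolerance = 1e-12)
  expect_identical(sp[1], sp[2])

  expect_error(group_speed(matrix(c(0.1, 0.1), 1, 2), 30), "insufficient")
})

test_that("inter-individual distance is the combined x/y population SD", {
  expect_equal(inter_individual_distance(matrix(c(0.3, 0.1), 5, 2, byrow = TRUE)), 0)

  a <- 0.2
  p <- rbind(c(0.4, 0.15), c(0.4, 0.15), c(0.4, 0.15),
             c(0.4 - a, 0.15), c(0.4 + a, 0.15))
  expect_equal(inter_individual_distance(p), sqrt(2 * a^2 / 5), tolerance = 1e-12)

  # algebraic identity: equals RMS distance to the shoal centre
  set.seed(42)
  for (r in 1:1000) {
    p <- random_frame()
    ctr <- colMeans(p)
    rms <- sqrt(mean((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2))
    expect_equal(inter_individual_distance(p), rms, tolerance = 1e-12)
  }

  # mean-distance alternative is the plain average distance to centre
  p <- random_frame()
  ctr <- colMeans(p)
  expect_equal(inter_individual_distance(p, method = "mean_dist"),
               mean(sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)))
})

test_that("alignment is the linear SD of body angles with axial-wrap warning", {
  expect_equal(alignment(rep(12, 5)), 0)
  expect_equal(alignment(c(-30, -15, 0, 15, 30)), sqrt(2250 / 4),
               tolerance = 1e-12)
  expect_equal(alignment(c(-30, -15, 0, 15, 30), divisor = "n"),
               sqrt(2250 / 5), tolerance = 1e-12)
  # near-parallel axes folded to opposite signs: large linear SD, flagged
  expect_warning(a <- alignment(c(-90, 90, -90, 90, 0)), "wrap")
  expect_gt(a, 80)
  expect_error(alignment(c(0, 0, 0, 0, 120)), "out of")
})

test_that("metric series aggregates per-frame metrics into 1-s bins", {
  tr <- calm_trial(duration_s = 10, onset_s = 5, drift_mps = 0.003)
  m <- metric_series(tr)
  expect_equal(nrow(m), 10)
  expect_equal(m$speed, rep(0.003, 10), tolerance = 1e-10)
  p0 <- cbind(tr$x[1, ], tr$y[1, ])
  expect_equal(m$iid, rep(inter_individual_distance(p0), 10), tolerance = 1e-10)
  expect_equal(m$alignment, rep(alignment(tr$angle[1, ]), 10), tolerance = 1e-10)

  # full-length trial: 90,000 frames at 30 frames/s -> 3,000 1-s samples
  big <- calm_trial(duration_s = 3000, onset_s = 1800, drift_mps = 0)
  expect_equal(nrow(big$x), 90000)
  expect_equal(nrow(metric_series(big)), 3000)

  # a step change in cohesion at onset appears within 1 s in the series
  tr2 <- calm_trial(duration_s = 10, onset_s = 5, drift_mps = 0)
  post <- (5 * 30 + 1):nrow(tr2$x)
  ctr_x <- rowMeans(tr2$x)
  tr2$x[post, ] <- 0.5 * tr2$x[post, ] + 0.5 * ctr_x[post]  # halve x-spread
  m2 <- metric_series(tr2)
  expect_lt(m2$iid[7], m2$iid[4])
  expect_equal(m2$iid[8], m2$iid[10], tolerance = 1e-10)
})

test_that("blocked summaries give per-window median and raw MAD", {
  bl <- block_summarise(rep(0.3, 90), window = 30)
  expect_equal(bl$median, rep(0.3, 3))
  expect_equal(bl$mad, rep(0, 3))

  one <- block_summarise(1:30, window = 30)
  expect_equal(one$median, 15.5)
  expect_equal(one$mad, 7.5)

  expect_error(block_summarise(1:10, window = 30), "shorter")

  # block medians of a monotone series are monotone
  bl2 <- block_summarise(sort(rnorm(630)), window = 30)
  expect_true(all(diff(bl2$median) > 0))
  expect_equal(nrow(bl2), 21)
})

test_that("deviation fraction counts disjoint median +/- MAD intervals", {
  set.seed(7)
  ctl <- block_summarise(rep(10, 630) + rnorm(630), window = 30)
  expect_equal(deviation_fraction(ctl, ctl)$fraction, 0)

  # exactly 3 of 21 blocks pushed out of reach
  trt <- ctl
  trt$median[c(2, 9, 17)] <- trt$median[c(2, 9, 17)] + 10
  d <- deviation_fraction(trt, ctl)
  expect_equal(d$fraction, 3 / 21)
  expect_equal(which(d$direction == "above"), c(2L, 9L, 17L))

  # all medians shifted beyond control median + mad, treatment mad 0
  up <- ctl; up$median <- ctl$median + ctl$mad + 1; up$mad <- 0
  d2 <- deviation_fraction(up, ctl)
  expect_equal(d2$fraction, 1)
  expect_true(all(d2$direction == "above"))

  # antisymmetry: swapping roles flips labels, preserves fraction
  d3 <- deviation_fraction(ctl, trt)
  expect_equal(d3$fraction, d$fraction)
  expect_true(all(d3$direction[d$direction == "above"] == "below"))

  expect_error(deviation_fraction(trt[1:10, ], ctl), "mismatched")
})

test_that("metrics are invariant under rigid motions of the group", {
  set.seed(99)
  p <- random_frame() * 0.3 + 0.02
  shift <- c(0.05, 0.01)
  p2 <- sweep(p, 2, shift, "+")
  expect_equal(inter_individual_distance(p2), inter_individual_distance(p))
  expect_equal(shoal_centre(p2), shoal_centre(p) + shift)

  # 90-degree rotation: swap and negate axes
  p3 <- cbind(-p[, 2] + 0.4, p[, 1])
  expect_equal(inter_individual_distance(p3), inter_individual_distance(p))

  a <- c(-30, -10, 0, 10, 25)
  expect_equal(alignment(a + 15), alignment(a))
})
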