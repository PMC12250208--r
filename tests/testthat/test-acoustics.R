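test_that("pulsed tones hit the requested SPL with exact ON/OFF gating", {
  w <- synth_tone(freq = 170, spl_db = 120, duration = 9)
  t <- (seq_along(w$samples) - 1) / w$sample_rate
  on <- (t %% 3) < 1
  rms_on <- sqrt(mean(w$samples[on]^2))
  expect_lt(abs(20 * log10(rms_on / 1e-6) - 120), 0.1)
  expect_true(all(w$samples[!on] == 0))

  # spectral peak at the tone frequency
  p <- psd_welch(w, nfft = 4096, overlap_fraction = 0.5)
  expect_equal(p$freq[which.max(p$psd)], 170, tolerance = w$sample_rate / 4096)

  expect_error(synth_tone(freq = 7000, spl_db = 100, duration = 1,
                          sample_rate = 12800), "Nyquist")
})

test_that("the masker is band-limited Gaussian noise at the requested level", {
  w <- synth_masker(spl_db = 110, duration = 10, seed = 4)
  expect_lt(abs(spl_rms(w) - 110), 0.1)

  w2 <- synth_masker(spl_db = 110, duration = 10, seed = 4)
  expect_identical(w$samples, w2$samples)

  # 8th-order Butterworth skirt: one octave below the 120-Hz edge the PSD
  # sits >= 40 dB below the in-band level
  p <- psd_welch(w, nfft = 4096, overlap_fraction = 0.5)
  inband <- mean(p$psd_db[p$freq > 500 & p$freq < 2000])
  below <- mean(p$psd_db[p$freq > 55 & p$freq < 65])
  expect_gte(inband - below, 40)

  expect_error(synth_masker(band = c(3000, 120)), "invalid band")
  expect_error(synth_masker(band = c(120, 9000), sample_rate = 12800),
               "invalid band")
})

test_that("Welch PSD has the stated bin width and integrates to the variance", {
  w <- synth_masker(spl_db = 110, duration = 6, sample_rate = 25600, seed = 9)
  p <- psd_welch(w, nfft = 8192, overlap_fraction = 0.915)
  expect_equal(diff(p$freq[1:2]), 25600 / 8192)  # 3.125 Hz ("3 Hz") bins

  set.seed(10)
  sigma <- 0.02
  wn <- waveform(rnorm(25600 * 4, 0, sigma), 25600)
  pw <- psd_welch(wn, nfft = 1024, overlap_fraction = 0.5)
  flat <- mean(pw$psd[pw$freq > 1000 & pw$freq < 11000])
  expect_lt(abs(flat - sigma^2 / 12800) / (sigma^2 / 12800), 0.10)
  expect_lt(abs(sum(pw$psd) * diff(pw$freq[1:2]) - var(wn$samples)) /
              var(wn$samples), 0.05)

  expect_error(psd_welch(waveform(rnorm(100), 1000), nfft = 1024), "exceeds")
})

test_that("SPL follows the 1-uPa reference", {
  fs <- 12800
  t <- (0:(fs - 1)) / fs
  expect_equal(spl_rms(waveform(sqrt(2) * sin(2 * pi * 200 * t), fs)), 120,
               tolerance = 1e-6)
  expect_equal(spl_rms(waveform(sqrt(2) * 1e-6 * sin(2 * pi * 200 * t), fs)), 0,
               tolerance = 1e-6)
  expect_warning(z <- spl_rms(waveform(rep(0, 100), fs)), "undefined")
  expect_identical(z, -Inf)
  # doubling pressure adds 6.02 dB
  w <- synth_masker(duration = 2, seed = 2)
  w2 <- waveform(2 * w$samples, w$sample_rate)
  expect_equal(spl_rms(w2) - spl_rms(w), 20 * log10(2), tolerance = 1e-9)
})

test_that("one-third-octave edges use base-2 ratios", {
  b <- third_octave_band(170)
  expect_equal(round(b[["f_lo"]]), 151)     # printed as "~ 151-190 Hz"
  expect_equal(floor(b[["f_hi"]]), 190)
  expect_equal(b[["f_lo"]], 170 * 2^(-1 / 6), tolerance = 1e-12)

  b2 <- third_octave_band(1000)
  expect_equal(b2, c(f_lo = 890.8987, f_hi = 1122.462), tolerance = 1e-6)
  for (f in c(50, 170, 2000))
    expect_equal(third_octave_band(f)[[2]] / third_octave_band(f)[[1]],
                 2^(1 / 3), tolerance = 1e-12)
})

test_that("SNR maps follow the pressure ratio and band correctly", {
  g <- make_pressure_fixture("uniform", list(amp = 0.5))
  expect_equal(as.vector(snr_map(g, g)), rep(0, 306), tolerance = 1e-12)

  g10 <- pressure_grid(g$shape, g$spacing, series = 10 * g$series,
                       sample_rate = g$sample_rate)
  expect_equal(as.vector(snr_map(g10, g)), rep(20, 306), tolerance = 1e-9)

  # banded SNR of tone + noise recovers the constructed in-band SNR
  sig <- make_pressure_fixture("tone_plus_noise",
                               list(snr_db = 20, duration = 0.5), seed = 21)
  noi <- make_pressure_fixture("noise",
                               list(snr_db = 20, duration = 0.5), seed = 21)
  snr <- snr_map(sig, noi, band = third_octave_band(170))
  # signal grid holds tone + noise, so expect 10*log10(1 + 10^(20/10))
  expect_lt(max(abs(snr - 10 * log10(1 + 100))), 0.5)
})

test_that("particle acceleration matches the plane-wave closed form", {
  uni <- make_pressure_fixture("uniform", list(amp = 1))
  acc <- particle_acceleration(uni)
  expect_true(all(acc$total == 0))
  expect_true(all(acc$db == -Inf))

  # plane wave A sin(wt - kx): total RMS acceleration = A k / (rho sqrt(2))
  A <- 2; k <- 0.7; dx <- 0.05  # k * dx = 0.035 <= 0.05
  pw <- make_pressure_fixture("plane_wave",
                              list(amp = A, k = k, freq = 160,
                                   duration = 0.5))
  apw <- particle_acceleration(pw)
  analytic <- A * k / (1000 * sqrt(2))
  expect_lt(max(abs(apw$total - analytic)) / analytic, 0.01)
  expect_true(all(abs(apw$ay) < 1e-12) && all(abs(apw$az) < 1e-12))

  # acceleration is linear in pressure and inversely proportional to rho
  pw2 <- pressure_grid(pw$shape, pw$spacing, series = 2 * pw$series,
                       sample_rate = pw$sample_rate, rho = 2000)
  expect_equal(particle_acceleration(pw2)$total, apw$total, tolerance = 1e-12)
  # doubling pressure alone adds 6.02 dB everywhere
  pw3 <- pressure_grid(pw$shape, pw$spacing, series = 2 * pw$series,
                       sample_rate = pw$sample_rate)
  expect_equal(particle_acceleration(pw3)$db - apw$db,
               array(20 * log10(2), dim(apw$db)), tolerance = 1e-9)
})

test_that("a field varying along one axis has only that component", {
  g <- make_pressure_fixture("axis_gradient", list(beta = 2, amp = 1))
  acc <- particle_acceleration(g)
  expect_true(all(abs(acc$ax) < 1e-12) && all(abs(acc$az) < 1e-12))
  d <- dim(acc$total)
  expect_equal(acc$total, acc$ay[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]),
                                 drop = FALSE], tolerance = 1e-12)
  # analytic: dp/dy amplitude = amp * beta -> RMS = amp*beta/sqrt(2)/rho
  expect_equal(mean(acc$ay), 1 * 2 / sqrt(2) / 1000, tolerance = 0.01)
})

test_that("finite differences converge to the analytic gradient at order ~2", {
  A <- 1; k <- 2; f <- 160
  err_at <- function(dx) {
    g <- make_pressure_fixture("plane_wave",
                               list(amp = A, k = k, freq = f, duration = 0.25,
                                    shape = c(9, 2, 2),
                                    spacing = c(dx, 0.05, 0.05)))
    a <- particle_acceleration(g)
    abs(mean(a$ax) - A * k / (1000 * sqrt(2)))
  }
  e1 <- err_at(0.4); e2 <- err_at(0.2)
  expect_gte(log2(e1 / e2), 1.9)
})

test_that("float WAV files round-trip with calibration", {
  w <- synth_tone(spl_db = 115, duration = 0.5)
  path <- tempfile(fileext = ".wav")
  wav_write(w, path, pa_per_unit = 0.05)
  back <- wav_read(path)
  expect_equal(back$sample_rate, w$sample_rate)
  expect_equal(back$samples, w$samples, tolerance = 1e-6)
  unlink(c(path, paste0(path, ".yaml")))
})
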