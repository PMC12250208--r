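#' Waveform container
#'
#' Calibrated sound-pressure time series in pascal.
#'
#' @param samples Numeric vector of sound pressure (Pa).
#' @param sample_rate Sampling rate in Hz.
#' @param label Optional text label.
#' @return Object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate, label = "") {
  if (!all(is.finite(samples))) stop("non-finite samples", call. = FALSE)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 label = label), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s: %d samples @ %g Hz (%.2f s), SPL %.1f dB re 1 uPa\n",
              x$label, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, spl_rms(x)))
  invisible(x)
}

# reference pressure for underwater SPL: 1 micropascal
P_REF <- 1e-6

#' Synthesise a pulsed tonal stimulus
#'
#' A sinusoid gated ON/OFF (default 1 s ON : 2 s OFF), with amplitude set
#' so that the RMS pressure over the ON segments equals the requested sound
#' pressure level re 1 uPa. OFF samples are exactly zero.
#'
#' @param freq Tone frequency in Hz (default 170).
#' @param spl_db Target SPL (RMS over ON segments), dB re 1 uPa.
#' @param duration Total duration in seconds.
#' @param on_s,off_s ON and OFF durations per pulse (s).
#' @param sample_rate Sampling rate in Hz (default 12800; must exceed
#'   `2 * freq`).
#' @return A [waveform()].
#' @export
synth_tone <- function(freq = 170, spl_db, duration, on_s = 1, off_s = 2,
                       sample_rate = 12800) {
  if (!is.finite(spl_db) || duration <= 0) stop("invalid spl_db or duration", call. = FALSE)
  if (freq >= sample_rate / 2) stop("freq at or above Nyquist", call. = FALSE)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  p_rms <- P_REF * 10^(spl_db / 20)
  x <- sqrt(2) * p_rms * sin(2 * pi * freq * t)
  gate <- (t %% (on_s + off_s)) < on_s
  waveform(x * gate, sample_rate,
           sprintf("tone %gHz %gdB", freq, spl_db))
}

#' Synthesise band-limited Gaussian masking noise
#'
#' Gaussian white noise band-passed with a Butterworth filter (default
#' order 8, 120-3000 Hz) and scaled so the broadband RMS pressure matches
#' the requested SPL. An optional additional high-pass (e.g. 100 Hz) mimics
#' loudspeaker protection filtering.
#'
#' @param band Pass band `c(f_lo, f_hi)` in Hz.
#' @param spl_db Target broadband SPL, dB re 1 uPa (default 110).
#' @param order Butterworth prototype order (even; default 8; skirts roll
#'   off at about `6 * order` dB per octave).
#' @param sample_rate Sampling rate in Hz (default 12800).
#' @param duration Duration in seconds.
#' @param highpass_hz Optional extra high-pass corner (Hz), `NULL` to skip.
#' @param seed Optional integer seed for reproducible noise.
#' @return A [waveform()].
#' @export
synth_masker <- function(band = c(120, 3000), spl_db = 110, order = 8,
                         sample_rate = 12800, duration = 10,
                         highpass_hz = NULL, seed = NULL) {
  nyq <- sample_rate / 2
  if (length(band) != 2L || band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop("invalid band: need 0 < f_lo < f_hi < Nyquist", call. = FALSE)
  if (order %% 2 != 0) stop("order must be even", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(round(duration * sample_rate))
  # two cascaded half-order sections: same asymptotic roll-off as a single
  # order-`order` section, numerically stable at narrow normalised bands
  bf <- signal::butter(order / 2, band / nyq, type = "pass")
  x <- as.numeric(signal::filter(bf, as.numeric(signal::filter(bf, x))))
  if (!is.null(highpass_hz)) {
    hf <- signal::butter(4, highpass_hz / nyq, type = "high")
    x <- as.numeric(signal::filter(hf, x))
  }
  p_rms <- P_REF * 10^(spl_db / 20)
  x <- x * (p_rms / sqrt(mean(x^2)))
  waveform(x, sample_rate,
           sprintf("masker %g-%gHz %gdB", band[1], band[2], spl_db))
}

# internal: periodic Hann window of length n
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Welch power spectral density
#'
#' One-sided Welch-averaged PSD with a Hann window and fractional segment
#' overlap. Bin width is `sample_rate / nfft`. The density integrates to
#' the signal variance (Parseval).
#'
#' @param wave A [waveform()] (or numeric vector with `sample_rate` given).
#' @param nfft Segment / FFT length (default 8192).
#' @param overlap_fraction Fractional overlap between segments in \[0, 1)
#'   (default 0.915).
#' @param sample_rate Required when `wave` is a bare numeric vector.
#' @return data.frame: `freq` (Hz), `psd` (Pa^2/Hz), `psd_db`
#'   (dB re 1 uPa^2/Hz).
#' @export
psd_welch <- function(wave, nfft = 8192, overlap_fraction = 0.915,
                      sample_rate = NULL) {
  if (inherits(wave, "waveform")) {
    x <- wave$samples; fs <- wave$sample_rate
  } else {
    x <- as.numeric(wave); fs <- sample_rate
    if (is.null(fs)) stop("sample_rate required for bare vectors", call. = FALSE)
  }
  if (nfft > length(x)) stop("nfft exceeds waveform length", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  step <- max(1L, round(nfft * (1 - overlap_fraction)))
  starts <- seq(1L, length(x) - nfft + 1L, by = step)
  w <- hann_window(nfft)
  norm <- fs * sum(w^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)] * w
    X <- fft(seg)[seq_along(acc)]
    acc <- acc + (Mod(X)^2) / norm
  }
  pxx <- acc / length(starts)
  # one-sided: double everything except DC and (for even nfft) Nyquist
  dbl <- rep(2, length(pxx)); dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[length(pxx)] <- 1
  pxx <- pxx * dbl
  freq <- (seq_along(pxx) - 1) * fs / nfft
  data.frame(freq = freq, psd = pxx,
             psd_db = 10 * log10(pmax(pxx, .Machine$double.xmin) / P_REF^2))
}

# internal: zero-phase brick-wall band-pass for band-limited RMS measures
# (exact unit gain in band; IIR designs are unreliable at the narrow
# normalised widths of 1/3-octave bands at these sample rates)
band_filter <- function(x, fs, band) {
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f_mir <- pmin(f, fs - f)
  keep <- f_mir >= band[1] & f_mir <= band[2]
  Re(fft(X * keep, inverse = TRUE)) / n
}

#' RMS sound pressure level
#'
#' `20 * log10(p_RMS / 1 uPa)`, optionally band-passed first. An all-zero
#' signal has no defined level and returns `-Inf` with a warning.
#'
#' @param wave A [waveform()].
#' @param band Optional `c(f_lo, f_hi)` band (Hz) applied before the RMS.
#' @return SPL in dB re 1 uPa.
#' @export
spl_rms <- function(wave, band = NULL) {
  stopifnot(inherits(wave, "waveform"))
  x <- wave$samples
  if (!length(x)) stop("empty waveform", call. = FALSE)
  if (!is.null(band)) x <- band_filter(x, wave$sample_rate, band)
  r <- sqrt(mean(x^2))
  if (r == 0) {
    warning("all-zero signal: SPL undefined (-Inf)")
    return(-Inf)
  }
  20 * log10(r / P_REF)
}

#' One-third-octave band edges
#'
#' Base-2 convention: `f_lo = centre * 2^(-1/6)`, `f_hi = centre * 2^(1/6)`,
#' so `f_hi / f_lo = 2^(1/3)`. This band approximates the auditory critical
#' band over which concurrent noise masks a tone at its centre.
#'
#' @param centre_hz Band centre frequency (Hz, > 0).
#' @return Named numeric vector `c(f_lo, f_hi)` in Hz.
#' @export
third_octave_band <- function(centre_hz) {
  stopifnot(centre_hz > 0)
  c(f_lo = centre_hz * 2^(-1 / 6), f_hi = centre_hz * 2^(1 / 6))
}

#' Write / read a float WAV file with a calibration sidecar
#'
#' Minimal 32-bit IEEE-float WAV writer/reader. Samples are stored in
#' arbitrary units; the pascal-per-unit calibration factor travels in a
#' YAML sidecar (`<path>.yaml`) so that read-back restores calibrated
#' pressure.
#'
#' @param wave A [waveform()].
#' @param path Output `.wav` path.
#' @param pa_per_unit Calibration factor; samples are divided by it on
#'   write and multiplied on read (default 1: store pascal directly).
#' @return `wav_write()` returns `path` invisibly; `wav_read()` a
#'   [waveform()].
#' @export
wav_write <- function(wave, path, pa_per_unit = 1) {
  stopifnot(inherits(wave, "waveform"))
  x <- wave$samples / pa_per_unit
  con <- file(path, "wb"); on.exit(close(con))
  n_bytes <- length(x) * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")            # IEEE float
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(wave$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(wave$sample_rate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(x, con, size = 4, endian = "little")
  yaml::write_yaml(list(pa_per_unit = pa_per_unit, label = wave$label,
                        sample_rate = wave$sample_rate),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname wav_write
#' @export
wav_read <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readChar(con, 4)
  if (hdr != "RIFF") stop("not a RIFF/WAV file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAV file", call. = FALSE)
  fmt <- NULL; samples <- NULL; fs <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!nzchar(id)) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, 2, endian = "little")
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 2, endian = "little"))
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (id == "data") {
      if (fmt == 3L) samples <- readBin(con, "double", sz / 4, 4, endian = "little")
      else if (fmt == 1L && bits == 16L)
        samples <- readBin(con, "integer", sz / 2, 2, signed = TRUE,
                           endian = "little") / 32768
      else stop("unsupported WAV encoding", call. = FALSE)
      break
    } else invisible(readBin(con, "raw", sz))
  }
  meta_path <- paste0(path, ".yaml")
  cal <- 1; label <- basename(path)
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    cal <- meta$pa_per_unit %||% 1
    label <- meta$label %||% label
  }
  waveform(samples * cal, fs, label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
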