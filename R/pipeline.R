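#' Run the full behavioural analysis
#'
#' Orchestrates the end-to-end chain on a set of trials: per-trial 1-s
#' group metric series; onset startle detection and continuous startle
#' counts; blocked median/MAD deviation fractions against the ambient
#' control; per-trial GLS slope CIs on inter-individual distance over the
#' exposure, classified against each noise condition's control normative
#' fit; contingency tables and SDT (d', c) per treatment at the coarse
#' (startle) and fine (inter-individual distance) scales; and ROC
#' artifacts.
#'
#' Noise trials for each treatment's false-alarm side are the matching
#' noise-condition control (AMB-C for ambient treatments, MASK-C for
#' masked). Control trials themselves are classified against their own
#' normative fit (optionally leave-one-out).
#'
#' @param dataset A `simulated_dataset`, or a list with `trials` (list of
#'   [trajectory_trial()]s).
#' @param corr Correlation structure for the GLS fits (`"ar1"` or
#'   `"none"`).
#' @param leave_one_out Logical: classify each control trial against a
#'   normative fit that excludes it (default `FALSE`).
#' @param startle_args List of arguments for [detect_onset_startles()].
#' @param block_window,n_blocks Blocked-summary parameters
#'   (see [block_summarise()]).
#' @param metric Fine-scale metric column (default `"iid"`).
#' @param out_dir Optional directory; when given, all report tables are
#'   written there as CSV plus a `provenance.json`.
#' @param seed Seed recorded in the provenance (the analysis itself is
#'   deterministic given its inputs).
#' @return A list of class `run_report`: `metrics` (per-trial series),
#'   `startle` (data.frame), `deviation_fractions`, `classifications`,
#'   `fine_cis`, `normative`, `tables` (per treatment x scale),
#'   `sdt` (list of [sdt()] results), `roc`, `provenance`.
#' @export
run_analysis <- function(dataset, corr = "ar1", leave_one_out = FALSE,
                         startle_args = list(), block_window = 30,
                         n_blocks = 21, metric = "iid", out_dir = NULL,
                         seed = NA_integer_) {
  trials <- dataset$trials
  if (!length(trials)) stop("no trials", call. = FALSE)
  treatments <- vapply(trials, `[[`, "", "treatment")
  for (ctl in c("AMB-C", "MASK-C"))
    if (!any(treatments == ctl))
      stop("missing control condition: ", ctl, call. = FALSE)

  # 1. per-trial metric series
  metrics <- lapply(trials, metric_series)

  # 2. startle detection + continuous counts
  startle_rows <- lapply(seq_along(trials), function(k) {
    tr <- trials[[k]]
    det <- do.call(detect_onset_startles, c(list(tr), startle_args))
    sched <- pulse_schedule(tr$onset_s,
                            n_pulses = floor((tr$offset_s - tr$onset_s) / 3))
    cc <- continuous_startle_count(sort(det$records$time_s), sched)
    data.frame(trial_id = tr$trial_id, treatment = tr$treatment,
               n_fish_startled = det$n_startled, continuous_count = cc)
  })
  startle <- do.call(rbind, startle_rows)

  # 3. fine-scale GLS classification against the normative fits
  exposure_series <- function(k) {
    tr <- trials[[k]]; m <- metrics[[k]]
    sel <- m$time_s >= tr$onset_s & m$time_s < tr$offset_s
    m[[metric]][sel]
  }
  t_common <- NULL
  series <- lapply(seq_along(trials), exposure_series)
  lens <- vapply(series, length, 1L)
  len <- min(lens)
  series <- lapply(series, function(s) s[seq_len(len)])
  t_common <- seq_len(len) - 1
  ctl_idx <- list("AMB" = which(treatments == "AMB-C"),
                  "MASK" = which(treatments == "MASK-C"))
  normative <- list(
    "AMB" = normative_fit(series[ctl_idx$AMB], t_common, corr = corr),
    "MASK" = normative_fit(series[ctl_idx$MASK], t_common, corr = corr))
  fine_cis <- lapply(series, gls_slope_ci, t = t_common, corr = corr)
  classify_one <- function(k) {
    cond <- if (startsWith(treatments[k], "AMB")) "AMB" else "MASK"
    is_ctl <- treatments[k] %in% c("AMB-C", "MASK-C")
    norm_ci <- if (is_ctl && leave_one_out) {
      others <- setdiff(ctl_idx[[cond]], k)
      normative_fit(series[others], t_common, corr = corr)
    } else normative[[cond]]
    classify_trial(fine_cis[[k]], norm_ci, signal_present = !is_ctl,
                   trial_id = trials[[k]]$trial_id)
  }
  classifications <- lapply(seq_along(trials), classify_one)

  # 4. contingency tables and SDT per treatment and scale
  signal_treatments <- setdiff(TREATMENTS, c("AMB-C", "MASK-C"))
  tables <- list(); sdt_results <- list()
  for (tr in signal_treatments) {
    cond <- if (startsWith(tr, "AMB")) "AMB" else "MASK"
    sig_idx <- which(treatments == tr)
    if (!length(sig_idx)) next
    noi_idx <- ctl_idx[[cond]]
    # coarse: startle presence / absence
    sig_resp <- startle$n_fish_startled[sig_idx] >= 1
    noi_resp <- startle$n_fish_startled[noi_idx] >= 1
    tab_c <- contingency_table(sum(sig_resp), sum(!sig_resp),
                               sum(noi_resp), sum(!noi_resp))
    # fine: CI deviation outcomes
    dev_sig <- vapply(classifications[sig_idx], `[[`, TRUE, "deviated")
    dev_noi <- vapply(classifications[noi_idx], `[[`, TRUE, "deviated")
    tab_f <- contingency_table(sum(dev_sig), sum(!dev_sig),
                               sum(dev_noi), sum(!dev_noi))
    tables[[paste0(tr, ".coarse")]] <- tab_c
    tables[[paste0(tr, ".fine")]] <- tab_f
    sdt_results[[paste0(tr, ".coarse")]] <- sdt(tab_c, paste0(tr, " coarse"))
    sdt_results[[paste0(tr, ".fine")]] <- sdt(tab_f, paste0(tr, " fine"))
  }
  roc <- list(
    coarse = roc_artifacts(sdt_results[grep("coarse", names(sdt_results))]),
    fine = roc_artifacts(sdt_results[grep("fine", names(sdt_results))]))

  # 5. blocked deviation fractions vs the ambient control, per metric
  block_start <- max(0, trials[[1]]$onset_s - block_window)
  pooled_blocks <- function(treat, met) {
    idx <- which(treatments == treat)
    vals <- do.call(cbind, lapply(idx, function(k) {
      m <- metrics[[k]]
      m[[met]][m$time_s >= block_start]
    }))
    nb <- min(n_blocks, floor(nrow(vals) / block_window))
    out <- data.frame(block_index = seq_len(nb),
                      block_start_s = block_start + (seq_len(nb) - 1) * block_window,
                      median = NA_real_, mad = NA_real_)
    for (b in seq_len(nb)) {
      v <- as.vector(vals[((b - 1) * block_window + 1):(b * block_window), ])
      out$median[b] <- median(v); out$mad[b] <- median(abs(v - median(v)))
    }
    class(out) <- c("blocked_series", "data.frame")
    out
  }
  dev_frac <- list()
  for (met in c("speed", "iid", "alignment")) {
    ref <- pooled_blocks("AMB-C", met)
    for (tr in setdiff(TREATMENTS, "AMB-C")) {
      if (!any(treatments == tr)) next
      d <- deviation_fraction(pooled_blocks(tr, met), ref)
      dev_frac[[paste0(tr, ".", met)]] <- d$fraction
    }
  }

  report <- structure(list(
    metrics = metrics, startle = startle,
    deviation_fractions = unlist(dev_frac),
    classifications = classifications, fine_cis = fine_cis,
    normative = normative, tables = tables, sdt = sdt_results, roc = roc,
    provenance = list(n_trials = length(trials), corr = corr,
                      leave_one_out = leave_one_out, metric = metric,
                      block_window = block_window, n_blocks = n_blocks,
                      seed = seed,
                      package_version = as.character(utils::packageVersion("shoalsdt")))),
    class = "run_report")
  if (!is.null(out_dir)) write_report(report, treatments, out_dir)
  report
}

# internal: serialise a run_report to CSV + JSON
write_report <- function(report, treatments, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$startle, file.path(out_dir, "startle_summary.csv"),
            row.names = FALSE)
  classification_report(report$classifications, report$fine_cis, treatments,
                        file.path(out_dir, "fine_classifications.csv"))
  sdt_summary(report$sdt, scale = sub(".*\\.", "", names(report$sdt)),
              path = file.path(out_dir, "sdt_summary.csv"))
  dev <- data.frame(key = names(report$deviation_fractions),
                    fraction = as.numeric(report$deviation_fractions))
  write.csv(dev, file.path(out_dir, "deviation_fractions.csv"),
            row.names = FALSE)
  for (scale in c("coarse", "fine"))
    write.csv(report$roc[[scale]]$points,
              file.path(out_dir, paste0("roc_points_", scale, ".csv")),
              row.names = FALSE)
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$provenance$n_trials, "trials\n")
  for (nm in names(x$sdt)) print(x$sdt[[nm]])
  invisible(x)
}

#' Characterise the sound field
#'
#' Acoustic counterpart of [run_analysis()]: Welch PSDs of the stimulus
#' waveforms, per-depth SPL maps of a signal grid, the banded SNR map
#' against a noise grid, and the finite-difference particle-acceleration
#' map.
#'
#' @param signal_grid [pressure_grid()] with time series of the tonal
#'   field.
#' @param noise_grid Matching grid of the masking-noise field.
#' @param waveforms Optional named list of [waveform()]s to characterise
#'   with [psd_welch()].
#' @param band Analysis band, default the one-third octave around 170 Hz.
#' @param nfft,overlap_fraction PSD parameters (defaults follow the
#'   mapping protocol: FFT 1024, 50% overlap).
#' @param out_dir Optional output directory for CSV maps.
#' @return List of class `acoustic_report`: `psd` (named list of PSD
#'   tables), `spl_map` (3-D array, dB re 1 uPa), `snr_map` (3-D array,
#'   dB), `accel` ([particle_acceleration()] output), `band`.
#' @export
run_acoustics <- function(signal_grid, noise_grid = NULL, waveforms = list(),
                          band = third_octave_band(170), nfft = 1024,
                          overlap_fraction = 0.5, out_dir = NULL) {
  stopifnot(inherits(signal_grid, "pressure_grid"))
  if (!is.null(noise_grid) &&
      !identical(signal_grid$shape, noise_grid$shape))
    stop("mismatched grid shapes", call. = FALSE)
  psds <- lapply(waveforms, psd_welch, nfft = nfft,
                 overlap_fraction = overlap_fraction)
  spl <- array(20 * log10(pmax(signal_grid$rms, .Machine$double.xmin) / P_REF),
               dim = signal_grid$shape)
  snr <- if (!is.null(noise_grid)) snr_map(signal_grid, noise_grid, band) else NULL
  accel <- if (!is.null(signal_grid$series)) particle_acceleration(signal_grid)
           else NULL
  rep <- structure(list(psd = psds, spl_map = spl, snr_map = snr,
                        accel = accel, band = band),
                   class = "acoustic_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sh <- signal_grid$shape
    idx <- expand.grid(x_idx = seq_len(sh[1]), y_idx = seq_len(sh[2]),
                       z_idx = seq_len(sh[3]))
    maps <- data.frame(idx, spl_db = as.vector(spl))
    if (!is.null(snr)) maps$snr_db <- as.vector(snr)
    write.csv(maps, file.path(out_dir, "field_maps.csv"), row.names = FALSE)
    if (!is.null(accel)) {
      shs <- dim(accel$total)
      ids <- expand.grid(x_idx = seq_len(shs[1]), y_idx = seq_len(shs[2]),
                         z_idx = seq_len(shs[3]))
      write.csv(data.frame(ids, accel_rms = as.vector(accel$total),
                           accel_db = as.vector(accel$db)),
                file.path(out_dir, "particle_acceleration.csv"),
                row.names = FALSE)
    }
    for (nm in names(psds))
      write.csv(psds[[nm]], file.path(out_dir, paste0("psd_", nm, ".csv")),
                row.names = FALSE)
  }
  rep
}
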