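# EEG/EMG preprocessing, band powers, rule-based sleep staging, and sleep
# architecture summaries.
#
# Staging follows the ratio rules used by rodent polysomnography scoring:
# within epochs where neck EMG is below the per-animal tone threshold and
# activity counts are zero, a delta ratio (delta power / total power) above
# 0.4 marks slow-wave sleep and a theta ratio (theta power / delta power)
# above 3 marks paradoxical (REM) sleep; everything else is wake.

#' Construct a physiological recording
#'
#' Bundles EEG and EMG series sampled at `sample_rate_hz` (typically 500 Hz)
#' with 1 Hz activity and temperature channels and a light/dark schedule.
#'
#' @param eeg,emg numeric vectors in microvolts, equal length.
#' @param activity integer activity counts at 1 Hz (one value per second).
#' @param temperature body temperature in degrees C at 1 Hz (optional).
#' @param sample_rate_hz sampling rate of `eeg`/`emg` in Hz.
#' @param start_clock_s clock time of the first sample, seconds after
#'   midnight.
#' @param lights_on_s,lights_off_s clock times (seconds after midnight) of the
#'   light-phase boundaries; lights on 07:00, off 19:00 by default.
#' @return An object of class `fad_recording`.
#' @export
recording <- function(eeg, emg, activity = NULL, temperature = NULL,
                      sample_rate_hz = 500,
                      start_clock_s = 12 * 3600,
                      lights_on_s = 7 * 3600, lights_off_s = 19 * 3600) {
  if (length(eeg) != length(emg))
    stop_invalid("eeg and emg must have equal length")
  check_scalar_number(sample_rate_hz, "sample_rate_hz", lower = 1)
  n_sec <- floor(length(eeg) / sample_rate_hz)
  if (is.null(activity)) activity <- integer(n_sec)
  if (is.null(temperature)) temperature <- rep(37, n_sec)
  structure(list(
    eeg = as.numeric(eeg), emg = as.numeric(emg),
    activity = as.numeric(activity), temperature = as.numeric(temperature),
    sample_rate_hz = sample_rate_hz,
    start_clock_s = start_clock_s,
    lights_on_s = lights_on_s, lights_off_s = lights_off_s
  ), class = "fad_recording")
}

#' @export
print.fad_recording <- function(x, ...) {
  cat(sprintf("<fad_recording> %.1f s at %g Hz (%d samples)\n",
              length(x$eeg) / x$sample_rate_hz, x$sample_rate_hz,
              length(x$eeg)))
  invisible(x)
}

#' Sleep-staging parameters
#'
#' @param epoch_length_s scoring epoch length in seconds (default 10).
#' @param delta_band_hz,theta_band_hz,total_band_hz band edges in Hz.
#' @param delta_ratio_threshold SWS calls require delta/total strictly above
#'   this value (default 0.4).
#' @param theta_ratio_threshold paradoxical-sleep calls require theta/delta
#'   strictly above this value (default 3).
#' @param emg_threshold_uV per-animal EMG RMS threshold in microvolts
#'   separating muscle tone from atonia (default 40, the midpoint of the
#'   usual 30-50 uV per-animal calibration range).
#' @param require_zero_activity if TRUE (default), any nonzero activity count
#'   in an epoch forces a wake call.
#' @return A list of class `staging_params`.
#' @export
staging_params <- function(epoch_length_s = 10,
                           delta_band_hz = c(0.5, 4),
                           theta_band_hz = c(4, 8),
                           total_band_hz = c(0.5, 80),
                           delta_ratio_threshold = 0.4,
                           theta_ratio_threshold = 3,
                           emg_threshold_uV = 40,
                           require_zero_activity = TRUE) {
  check_scalar_number(epoch_length_s, "epoch_length_s", lower = 1e-6)
  check_scalar_number(delta_ratio_threshold, "delta_ratio_threshold", lower = 1e-12)
  check_scalar_number(theta_ratio_threshold, "theta_ratio_threshold", lower = 1e-12)
  check_scalar_number(emg_threshold_uV, "emg_threshold_uV", lower = 1e-12)
  check_flag(require_zero_activity, "require_zero_activity")
  bands_ok <- delta_band_hz[1] >= total_band_hz[1] &&
    theta_band_hz[2] <= total_band_hz[2]
  if (!bands_ok) stop_invalid("delta/theta bands must nest inside the total band")
  structure(list(
    epoch_length_s = epoch_length_s,
    delta_band_hz = delta_band_hz, theta_band_hz = theta_band_hz,
    total_band_hz = total_band_hz,
    delta_ratio_threshold = delta_ratio_threshold,
    theta_ratio_threshold = theta_ratio_threshold,
    emg_threshold_uV = emg_threshold_uV,
    require_zero_activity = require_zero_activity
  ), class = "staging_params")
}

#' Band-pass and notch filter a recording
#'
#' Applies a zero-phase 4th-order Butterworth band-pass (0.5-80 Hz) plus a
#' 2nd-order 60 Hz notch to the EEG, and a 10-100 Hz band-pass to the EMG.
#' Zero-phase (forward-backward) filtering preserves spike morphology, which
#' matters for the downstream spike-wave detector.
#'
#' @param rec a `fad_recording`.
#' @param eeg_band_hz,notch_hz,emg_band_hz filter edges in Hz.
#' @return The recording with filtered `eeg` and `emg`; length preserved.
#' @export
preprocess_recording <- function(rec, eeg_band_hz = c(0.5, 80), notch_hz = c(58, 62),
                                 emg_band_hz = c(10, 100)) {
  stopifnot(inherits(rec, "fad_recording"))
  if (anyNA(rec$eeg) || anyNA(rec$emg))
    stop_invalid("recording contains NaN/NA samples")
  fs <- rec$sample_rate_hz
  if (fs < 200) stop_invalid("sample rate must be at least 200 Hz")
  nyq <- fs / 2
  bp <- signal::butter(4, eeg_band_hz / nyq, type = "pass")
  notch <- signal::butter(2, notch_hz / nyq, type = "stop")
  emg_bp <- signal::butter(4, emg_band_hz / nyq, type = "pass")
  rec$eeg <- signal::filtfilt(notch, signal::filtfilt(bp, rec$eeg))
  rec$emg <- signal::filtfilt(emg_bp, rec$emg)
  rec
}

band_power_from_pgram <- function(pgram, freqs, band) {
  sum(pgram[freqs > band[1] & freqs <= band[2]])
}

#' Per-epoch FFT band powers and staging features
#'
#' Splits the recording into consecutive epochs (any trailing partial epoch is
#' dropped), computes the periodogram of each EEG epoch by FFT, and integrates
#' power over the delta, theta and total bands. Band membership uses
#' left-open/right-closed intervals so the shared 4 Hz edge belongs to delta
#' only. Also reports per-epoch EMG RMS and summed activity counts.
#'
#' @param rec a (typically preprocessed) `fad_recording`.
#' @param params a `staging_params` object.
#' @return A data.frame with one row per epoch: `epoch_start_s`,
#'   `delta_power`, `theta_power`, `total_power`, `delta_ratio`
#'   (delta/total), `theta_ratio` (theta/delta), `emg_rms`, `activity_sum`.
#' @export
epoch_band_powers <- function(rec, params = staging_params()) {
  stopifnot(inherits(rec, "fad_recording"))
  fs <- rec$sample_rate_hz
  n_ep_samp <- round(params$epoch_length_s * fs)
  if (n_ep_samp < 1) stop_invalid("epoch length must cover at least one sample")
  n_epochs <- floor(length(rec$eeg) / n_ep_samp)
  if (n_epochs < 1) stop_invalid("recording shorter than one epoch")
  freqs <- (seq_len(n_ep_samp) - 1) * fs / n_ep_samp
  half <- freqs <= fs / 2
  out <- vector("list", n_epochs)
  sec_per_epoch <- params$epoch_length_s
  for (e in seq_len(n_epochs)) {
    idx <- ((e - 1) * n_ep_samp + 1):(e * n_ep_samp)
    x <- rec$eeg[idx]
    pg <- Mod(fft(x))^2 / n_ep_samp
    pg <- pg[half]
    fr <- freqs[half]
    d <- band_power_from_pgram(pg, fr, params$delta_band_hz)
    th <- band_power_from_pgram(pg, fr, params$theta_band_hz)
    tot <- band_power_from_pgram(pg, fr, params$total_band_hz)
    emg_rms <- sqrt(mean(rec$emg[idx]^2))
    sec_idx <- floor((e - 1) * sec_per_epoch) + seq_len(ceiling(sec_per_epoch))
    sec_idx <- sec_idx[sec_idx <= length(rec$activity)]
    out[[e]] <- c(epoch_start_s = (e - 1) * sec_per_epoch,
                  delta_power = d, theta_power = th, total_power = tot,
                  delta_ratio = if (tot > 0) d / tot else 0,
                  theta_ratio = if (d > 0) th / d else Inf,
                  emg_rms = emg_rms,
                  activity_sum = sum(rec$activity[sec_idx]))
  }
  as.data.frame(do.call(rbind, out))
}

#' Classify one epoch into a sleep stage
#'
#' Gate first on muscle tone and movement: an epoch with EMG RMS at or above
#' the threshold, or any activity counts, is WAKE. Among inactive epochs a
#' theta ratio strictly above the threshold is PARADOXICAL, otherwise a delta
#' ratio strictly above its threshold is SWS; inactive epochs failing both
#' ratio tests are scored as (quiet) WAKE.
#'
#' @param delta_ratio delta power / total power for the epoch.
#' @param theta_ratio theta power / delta power for the epoch.
#' @param emg_rms epoch EMG RMS in microvolts.
#' @param activity_sum summed activity counts in the epoch.
#' @param params a `staging_params` object.
#' @return One of `"WAKE"`, `"SWS"`, `"PARADOXICAL"` (vectorized over inputs).
#' @export
classify_epoch <- function(delta_ratio, theta_ratio, emg_rms, activity_sum = 0,
                           params = staging_params()) {
  n <- max(length(delta_ratio), length(theta_ratio), length(emg_rms),
           length(activity_sum))
  delta_ratio <- rep_len(delta_ratio, n)
  theta_ratio <- rep_len(theta_ratio, n)
  emg_rms <- rep_len(emg_rms, n)
  activity_sum <- rep_len(activity_sum, n)
  if (any(delta_ratio < 0, na.rm = TRUE) || any(emg_rms < 0, na.rm = TRUE) ||
      any(theta_ratio < 0, na.rm = TRUE))
    stop_invalid("ratios and EMG RMS must be non-negative")
  awake <- emg_rms >= params$emg_threshold_uV |
    (params$require_zero_activity & activity_sum > 0)
  stage <- rep("WAKE", n)
  inactive <- !awake
  stage[inactive & theta_ratio > params$theta_ratio_threshold] <- "PARADOXICAL"
  stage[inactive & theta_ratio <= params$theta_ratio_threshold &
          delta_ratio > params$delta_ratio_threshold] <- "SWS"
  stage
}

#' Stage a whole recording
#'
#' Composition of \code{\link{preprocess_recording}},
#' \code{\link{epoch_band_powers}} and \code{\link{classify_epoch}}.
#'
#' @param rec a raw `fad_recording`.
#' @param params a `staging_params` object.
#' @param preprocess apply the filters first (default TRUE).
#' @return A hypnogram data.frame (`epoch_start_s`, `stage`) with the epoch
#'   length and light schedule attached as attributes.
#' @export
stage_recording <- function(rec, params = staging_params(), preprocess = TRUE) {
  if (preprocess) rec <- preprocess_recording(rec)
  feats <- epoch_band_powers(rec, params)
  hyp <- data.frame(
    epoch_start_s = feats$epoch_start_s,
    stage = classify_epoch(feats$delta_ratio, feats$theta_ratio,
                           feats$emg_rms, feats$activity_sum, params),
    stringsAsFactors = FALSE
  )
  attr(hyp, "epoch_length_s") <- params$epoch_length_s
  attr(hyp, "start_clock_s") <- rec$start_clock_s
  attr(hyp, "lights_on_s") <- rec$lights_on_s
  attr(hyp, "lights_off_s") <- rec$lights_off_s
  hyp
}

epoch_period <- function(epoch_start_s, start_clock_s, lights_on_s, lights_off_s) {
  clock <- (start_clock_s + epoch_start_s) %% 86400
  ifelse(clock >= lights_on_s & clock < lights_off_s, "light", "dark")
}

#' Summarize sleep architecture by activity period
#'
#' Run-length encodes the hypnogram into stage episodes, splitting episodes at
#' light/dark transitions, and reports per period (light = inactive, dark =
#' active) the minutes spent in each stage, the episode count, and the mean
#' episode duration (total stage time / episode count).
#'
#' @param hypnogram data.frame with `epoch_start_s` and `stage`; epoch length
#'   and the light schedule are read from its attributes unless supplied.
#' @param epoch_length_s,start_clock_s,lights_on_s,lights_off_s overrides for
#'   the hypnogram attributes.
#' @return A data.frame with columns `period`, `stage`, `minutes`,
#'   `episodes`, `mean_episode_s`.
#' @export
summarize_sleep <- function(hypnogram,
                            epoch_length_s = attr(hypnogram, "epoch_length_s"),
                            start_clock_s = attr(hypnogram, "start_clock_s"),
                            lights_on_s = attr(hypnogram, "lights_on_s"),
                            lights_off_s = attr(hypnogram, "lights_off_s")) {
  if (is.null(epoch_length_s))
    stop_invalid("epoch_length_s not found; supply it explicitly")
  if (is.null(start_clock_s)) start_clock_s <- 0
  if (is.null(lights_on_s) || is.null(lights_off_s))
    stop_invalid("light schedule not found; supply lights_on_s/lights_off_s")
  period <- epoch_period(hypnogram$epoch_start_s, start_clock_s,
                         lights_on_s, lights_off_s)
  # episode boundaries: stage change OR period change
  key <- paste(hypnogram$stage, period, sep = "\r")
  runs <- rle(key)
  ep_stage <- sub("\r.*$", "", runs$values)
  ep_period <- sub("^.*\r", "", runs$values)
  ep_minutes <- runs$lengths * epoch_length_s / 60
  out <- expand.grid(period = c("light", "dark"),
                     stage = c("WAKE", "SWS", "PARADOXICAL"),
                     stringsAsFactors = FALSE)
  out$minutes <- 0
  out$episodes <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- ep_stage == out$stage[i] & ep_period == out$period[i]
    out$minutes[i] <- sum(ep_minutes[sel])
    out$episodes[i] <- sum(sel)
  }
  out$mean_episode_s <- ifelse(out$episodes > 0,
                               out$minutes * 60 / out$episodes, NA_real_)
  out
}
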